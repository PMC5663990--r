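test_that("tumor margin equals the analytic shell, with overlap as union", {
  # sphere of radius 10 mm in a big liver: margin-11 shell is 10 < d <= 21
  dims <- c(30, 30, 30); sp <- 2
  gg <- expand.grid(x = 1:30, y = 1:30, z = 1:30)
  ctr <- c(30, 30, 30)
  d_ctr <- sqrt(((gg$x - 0.5) * sp - ctr[1])^2 + ((gg$y - 0.5) * sp - ctr[2])^2 +
                  ((gg$z - 0.5) * sp - ctr[3])^2)
  tum <- array(d_ctr <= 10, dims)
  liv <- array(TRUE, dims)
  mg <- tumor_margin(as_volume(tum, sp), as_volume(liv, sp), 11)
  # oracle: distance from each voxel center to the nearest tumor voxel center
  tidx <- which(tum, arr.ind = TRUE)
  tpos <- sweep(tidx - 0.5, 2, rep(sp, 3), "*")
  vox <- (as.matrix(gg) - 0.5) * sp
  dmin2 <- rep(Inf, nrow(vox))
  for (i in seq_len(nrow(tpos)))
    dmin2 <- pmin(dmin2, (vox[, 1] - tpos[i, 1])^2 + (vox[, 2] - tpos[i, 2])^2 +
                    (vox[, 3] - tpos[i, 3])^2)
  want <- array(sqrt(dmin2) <= 11, dims) & !tum
  expect_identical(vdata(mg), want)

  # zero margin is empty; overlapping margins union without double counting
  expect_equal(sum(tumor_margin(as_volume(tum, sp), as_volume(liv, sp), 0)), 0)
  tum2 <- tum; tum2[1:4, 1:4, 1:4] <- TRUE
  mg2 <- tumor_margin(as_volume(tum2, sp), as_volume(liv, sp), 11)
  expect_true(all(vdata(mg2)[vdata(mg) & !tum2]))
  expect_false(any(vdata(mg2) & tum2))
})

test_that("margin cannot consume the whole normal liver", {
  dims <- c(8, 8, 8)
  tum <- array(FALSE, dims); tum[4, 4, 4] <- TRUE
  liv <- array(FALSE, dims); liv[3:5, 3:5, 3:5] <- TRUE
  expect_error(tumor_margin(as_volume(tum, 2), as_volume(liv, 2), 50),
               "entire normal liver")
})

test_that("partition counting books every count exactly once", {
  ph <- default_phantom()
  tab <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                          ph$lung_mask, capture_mm = 10)
  # exact count conservation including the background remainder
  expect_identical(sum(tab$counts) + attr(tab, "background_counts"),
                   sum(vdata(ph$count_image)))
  expect_equal(sum(tab$role == "lung"), 1L)
  expect_gte(sum(tab$role == "normal_liver_territory"), 1L)

  # margin bookkeeping: NL counts drop by exactly the margin-voxel sum
  tab0 <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                           ph$lung_mask, margin = margin_policy(0))
  tab11 <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                            ph$lung_mask, margin = margin_policy(11))
  nl0 <- sum(tab0$counts[tab0$role == "normal_liver_territory"])
  nl11 <- sum(tab11$counts[tab11$role == "normal_liver_territory"])
  mgc <- sum(tab11$counts[tab11$role == "excluded_margin"])
  expect_equal(nl0, nl11 + mgc)

  # margin dispositions: merge books the same counts into tumors; drop
  # sends them to the background remainder
  tabm <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                           ph$lung_mask,
                           margin = margin_policy(11, "merge_into_tumor"))
  expect_equal(sum(tabm$counts[tabm$role == "tumor"]),
               sum(tab11$counts[tab11$role == "tumor"]) + mgc)
  tabd <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                           ph$lung_mask, margin = margin_policy(11, "drop"))
  expect_equal(attr(tabd, "background_counts"),
               attr(tab11, "background_counts") + mgc)
})

test_that("uniform counts split in proportion to territory volume", {
  dims <- c(12, 12, 12)
  lab <- array(0L, dims); lab[2:11, 2:6, 2:11] <- 1L; lab[2:11, 7:11, 2:11] <- 2L
  cts <- as_volume(array(1, dims), 3)
  lung <- array(FALSE, dims)
  tum <- array(FALSE, dims)
  tab <- partition_counts(cts, as_volume(lab, 3), as_volume(tum, 3),
                          as_volume(lung, 3), margin = margin_policy(0))
  nl <- tab[tab$role == "normal_liver_territory", ]
  expect_equal(nl$counts[1], nl$counts[2])
  expect_equal(nl$volume_mL[1], nl$volume_mL[2])
})

test_that("shunt and T/N evaluate their defining ratios", {
  t1 <- make_table(c("lung", "normal_liver_territory", "tumor"),
                   counts = c(10, 60, 30), masses = c(1, 1.2, 0.1))
  expect_equal(lung_shunt_fraction(t1), 0.1)
  expect_equal(tn_ratio(t1), (30 / 0.1) / (60 / 1.2))
  t0 <- make_table(c("lung", "normal_liver_territory"), c(0, 50), c(1, 1.2))
  expect_equal(lung_shunt_fraction(t0), 0)
  tall <- make_table(c("lung", "normal_liver_territory"), c(50, 0), c(1, 1.2))
  expect_equal(lung_shunt_fraction(tall), 1)
  # equal densities give T/N = 1
  teq <- make_table(c("lung", "normal_liver_territory", "tumor"),
                    c(0, 120, 10), c(1, 1.2, 0.1))
  expect_equal(tn_ratio(teq), 1)
  # guards
  tz <- make_table(c("lung", "normal_liver_territory", "tumor"),
                   c(0, 60, 30), c(1, 1.2, 0))
  expect_error(tn_ratio(tz), "undefined")
  tnc <- make_table(c("lung", "normal_liver_territory", "tumor"),
                    c(0, 0, 30), c(1, 1.2, 0.1))
  expect_error(tn_ratio(tnc), "undefined")
})

test_that("noiseless unblurred phantom counts recover the ground truth exactly", {
  spec <- phantom_spec(psf_fwhm_mm = 0)
  ph <- build_phantom(spec, poisson = FALSE)
  tab <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                          ph$lung_mask, margin = margin_policy(0))
  expect_equal(lung_shunt_fraction(tab), 0.1, tolerance = 1e-6)
  expect_equal(tn_ratio(tab), 6, tolerance = 1e-6)
})

test_that("masses scale with voxel count, volume and density", {
  lab <- as_volume(array(rep(c(0L, 1L), each = 500), c(10, 10, 10)), 1)
  pm <- partition_masses(lab, density_kg_per_L = 1.05)
  expect_equal(pm$mass_kg, 500 * 1e-3 / 1000 * 1.05) # 500 mm^3 at 1.05 kg/L
  pm2 <- partition_masses(lab, density_kg_per_L = 2.1)
  expect_equal(pm2$mass_kg, 2 * pm$mass_kg)
  lab2 <- as_volume(array(c(rep(1L, 500), rep(3L, 500)), c(10, 10, 10)), 1)
  pm3 <- partition_masses(lab2)
  expect_true(pm3$empty[2])
  expect_equal(pm3$mass_kg[2], 0)
})
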