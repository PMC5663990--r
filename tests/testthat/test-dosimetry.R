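test_that("single-compartment dose follows the MIRD factor", {
  dc <- dose_constants()
  expect_equal(round(dc$dose_factor_Gy_kg_per_GBq, 2), 49.38)
  expect_equal(dose_simple(1, 1), dc$dose_factor_Gy_kg_per_GBq)
  expect_equal(dose_simple(0, 2), 0)
  # A = 2 GBq in a mass equal to the factor gives exactly 2 Gy
  expect_equal(dose_simple(2, dc$dose_factor_Gy_kg_per_GBq), 2)
  expect_error(dose_simple(1, 0), "mass")
})

test_that("classical partition doses match an independent hand evaluation", {
  k <- dose_constants()$dose_factor_Gy_kg_per_GBq
  d <- pm_doses(A0_GBq = 1, L = 0.1, TN = 4, m_lung_kg = 1, m_nl_kg = 1.5,
                m_tumor_kg = 0.25)
  expect_equal(d$D_lung_Gy, k * 1 * 0.1 / 1)
  expect_equal(d$D_nl_Gy, k * 1 * 0.9 / (1.5 + 4 * 0.25))
  expect_equal(d$D_tumor_Gy, 4 * d$D_nl_Gy)

  # L = 0, TN = 1: both liver compartments get the pooled dose
  d2 <- pm_doses(1, 0, 1, 1, 0.75, 0.25)
  expect_equal(d2$D_nl_Gy, k / 1)
  expect_equal(d2$D_tumor_Gy, d2$D_nl_Gy)

  # identity D_T / D_NL = TN over random draws
  set.seed(1)
  for (i in 1:25) {
    tn <- runif(1, 0.5, 12)
    d3 <- pm_doses(runif(1, 0.5, 5), runif(1, 0, 0.6), tn, runif(1, 0.5, 2),
                   runif(1, 0.8, 2.5), runif(1, 0.01, 0.8))
    expect_equal(d3$D_tumor_Gy / d3$D_nl_Gy, tn, tolerance = 1e-12)
  }
})

test_that("fractional uptake is a normalized share with a zero-activity limit", {
  expect_equal(fractional_uptake(5), 1)
  expect_equal(fractional_uptake(c(3, 3)), c(0.5, 0.5))
  expect_equal(fractional_uptake(c(0, 7)), c(0, 1)) # limit, no division
  set.seed(2)
  for (i in 1:20) {
    a <- runif(sample(2:8, 1), 0, 10)
    expect_equal(sum(fractional_uptake(a)), 1)
  }
  expect_error(fractional_uptake(c(0, 0)), "total")
})

test_that("territorial doses reduce to the classical model for {NL, T}", {
  set.seed(3)
  for (i in 1:50) {
    m_l <- runif(1, 0.5, 2); m_nl <- runif(1, 0.8, 2.5); m_t <- runif(1, 0.02, 0.8)
    c_l <- runif(1, 0, 5e4); c_nl <- runif(1, 1e4, 1e6); c_t <- runif(1, 1e3, 5e5)
    A0 <- runif(1, 0.5, 6)
    tab <- make_table(c("lung", "normal_liver_territory", "tumor"),
                      c(c_l, c_nl, c_t), c(m_l, m_nl, m_t))
    L <- c_l / (c_l + c_nl + c_t)
    TN <- (c_t / m_t) / (c_nl / m_nl)
    dosed <- tm_doses(A0, tab)
    ref <- pm_doses(A0, L, TN, m_l, m_nl, m_t)
    expect_equal(dosed$dose_Gy[dosed$role == "normal_liver_territory"],
                 ref$D_nl_Gy, tolerance = 1e-10)
    expect_equal(dosed$dose_Gy[dosed$role == "tumor"], ref$D_tumor_Gy,
                 tolerance = 1e-10)
    expect_equal(dosed$dose_Gy[dosed$role == "lung"], ref$D_lung_Gy,
                 tolerance = 1e-10)
  }
})

test_that("liver-side doses conserve the delivered energy", {
  k <- dose_constants()$dose_factor_Gy_kg_per_GBq
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:9, 1)
    roles <- c("lung", sample(c("normal_liver_territory", "tumor",
                                "excluded_margin"), n, TRUE),
               "normal_liver_territory")
    counts <- c(runif(1, 0, 1e4), runif(n + 1, 1e2, 1e5))
    masses <- runif(n + 2, 0.05, 2)
    tab <- tm_doses(2.5, make_table(roles, counts, masses))
    liver <- tab$role != "lung"
    L <- lung_shunt_fraction(tab)
    expect_equal(sum(tab$dose_Gy[liver] * tab$mass_kg[liver]),
                 k * 2.5 * (1 - L), tolerance = 1e-9)
  }
  # a liver partition with zero counts receives zero dose
  tab0 <- tm_doses(1, make_table(c("lung", "normal_liver_territory", "tumor"),
                                 c(0, 100, 0), c(1, 1, 0.1)))
  expect_equal(tab0$dose_Gy[tab0$role == "tumor"], 0)
})

test_that("doses are linear in activity and ordered in the shunt fraction", {
  tab <- make_table(c("lung", "normal_liver_territory", "tumor"),
                    c(500, 8000, 1500), c(1, 1.4, 0.2))
  d1 <- tm_doses(1, tab); d2 <- tm_doses(2, tab)
  expect_equal(d2$dose_Gy, 2 * d1$dose_Gy, tolerance = 1e-12)
  # larger shunt: more lung dose, less liver dose at fixed A0
  k <- dose_constants()$dose_factor_Gy_kg_per_GBq
  dlo <- tm_doses(1, tab, L = 0.05); dhi <- tm_doses(1, tab, L = 0.3)
  expect_gt(dhi$dose_Gy[dhi$role == "lung"], dlo$dose_Gy[dlo$role == "lung"])
  expect_true(all(dhi$dose_Gy[dhi$role != "lung"] <
                    dlo$dose_Gy[dlo$role != "lung"]))
})

test_that("mean normal-liver dose equals the pooled dose under mass weighting", {
  tab <- make_table(c("lung", "normal_liver_territory", "normal_liver_territory"),
                    c(0, 100, 300), c(1, 0.5, 0.5))
  dosed <- tm_doses(1, tab)
  nl <- dosed[dosed$role == "normal_liver_territory", ]
  # equal masses, doses d and 3d -> mean 2d (both weightings agree)
  expect_equal(mean_normal_liver_dose(dosed), mean(nl$dose_Gy))
  k <- dose_constants()$dose_factor_Gy_kg_per_GBq
  expect_equal(mean_normal_liver_dose(dosed), k * 1 * 1 * 1 / 1) # all counts NL, mass 1
  # pooled identity with unequal masses
  tab2 <- tm_doses(1.7, make_table(
    c("lung", "normal_liver_territory", "normal_liver_territory", "tumor"),
    c(100, 4000, 2500, 900), c(1, 1.1, 0.4, 0.1)))
  L <- lung_shunt_fraction(tab2)
  f_nl <- sum(tab2$counts[tab2$role == "normal_liver_territory"]) /
    sum(tab2$counts[tab2$role != "lung"])
  m_nl <- sum(tab2$mass_kg[tab2$role == "normal_liver_territory"])
  expect_equal(mean_normal_liver_dose(tab2), k * 1.7 * (1 - L) * f_nl / m_nl,
               tolerance = 1e-12)
})

test_that("dose maps are piecewise constant and round-trip the table", {
  ph <- default_phantom()
  tab <- partition_counts(ph$count_image, ph$territory_truth, ph$tumor_mask,
                          ph$lung_mask, capture_mm = 10)
  dosed <- tm_doses(3, tab)
  dm <- render_dose_map(dosed)
  m <- vdata(dm)
  lab <- vdata(attr(dosed, "label_map"))
  # margin sentinel distinct from zero and from real doses
  mg_id <- dosed$partition[dosed$role == "excluded_margin"]
  expect_true(all(m[lab %in% mg_id] == -1))
  # every other labeled voxel carries its partition's dose exactly
  for (r in which(dosed$role != "excluded_margin" & !dosed$empty)) {
    sel <- lab == dosed$partition[r]
    expect_equal(unique(m[sel]), dosed$dose_Gy[r], tolerance = 1e-12)
  }
  expect_true(all(m[lab == 0L] == 0))
  # distinct non-zero values bounded by partition count
  expect_lte(length(setdiff(unique(as.vector(m)), 0)), nrow(dosed) + 1)
})
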