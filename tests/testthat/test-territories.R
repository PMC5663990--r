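test_that("thinning recovers the axis of a voxel-centered cylinder", {
  dims <- c(17, 17, 40)
  g <- expand.grid(x = 1:17, y = 1:17, z = 1:40)
  cyl <- array((g$x - 9)^2 + (g$y - 9)^2 <= 9 & g$z >= 3 & g$z <= 38, dims)
  sk <- skeletonize_vessels(as_volume(cyl, 1))
  expect_true(all(vdata(sk)[!cyl] == FALSE)) # contained in the mask
  idx <- which(vdata(sk), arr.ind = TRUE)
  dax <- sqrt((idx[, 1] - 9)^2 + (idx[, 2] - 9)^2)
  expect_gte(mean(dax <= 1), 0.95)
  # single-voxel-wide result
  gr <- build_centerline_graph(sk)
  expect_length(gr$branches, 1L)
})

test_that("an already-thin curve passes through thinning unchanged", {
  a <- array(FALSE, c(9, 9, 30))
  a[5, 5, 3:27] <- TRUE
  a[5, 6, 28] <- TRUE # small kink, still single-voxel-wide
  sk <- skeletonize_vessels(as_volume(a, 1))
  expect_identical(vdata(sk), a)
})

test_that("a Y-shaped tube yields three branches around one bifurcation", {
  a <- array(FALSE, c(41, 41, 21))
  a <- rasterize_segment(a, c(21, 21, 11), c(21, 5, 11), 2)
  a <- rasterize_segment(a, c(21, 21, 11), c(9, 35, 11), 2)
  a <- rasterize_segment(a, c(21, 21, 11), c(33, 35, 11), 2)
  sk <- skeletonize_vessels(as_volume(a, 1))
  # topology preserved: one connected component
  comp <- label_components(sk)
  expect_equal(max(vdata(comp)), 1L)
  gr <- build_centerline_graph(sk)
  expect_length(gr$branches, 3L)
  expect_equal(sum(gr$nodes$kind == "bifurcation"), 1L)
  expect_equal(sum(gr$nodes$kind %in% c("endpoint", "root")), 3L)
})

test_that("graph construction handles straight paths and the phantom's strict tree", {
  a <- array(FALSE, c(7, 7, 20)); a[4, 4, 3:17] <- TRUE
  gr <- build_centerline_graph(as_volume(a, 1))
  expect_length(gr$branches, 1L)
  expect_equal(nrow(gr$nodes), 2L)

  ph <- default_phantom()
  sk <- skeletonize_vessels(ph$vessel_mask)
  g <- build_centerline_graph(sk, root_hint = ph$spec$vessel_root_mm)
  expect_length(g$branches, 2^ph$spec$generations - 1)
})

test_that("single-branch and symmetric two-branch assignments behave analytically", {
  # single branch: everything is territory 1
  box <- as_volume(array(TRUE, c(10, 10, 10)), 2)
  nodes <- data.frame(id = 1:2, x = c(10, 10), y = c(10, 10), z = c(2, 18),
                      kind = c("root", "endpoint"))
  br <- list(list(id = 1L, from = 1L, to = 2L,
                  points = cbind(10, 10, seq(2, 18, by = 1)),
                  parent = NA_integer_, generation = 1L))
  g1 <- centerline_graph(nodes, br, 1L)
  t1 <- assign_territories(box, g1, grouping = c("1" = 1L))
  expect_true(all(vdata(t1$labels) == 1L))

  # two parallel vertical lines at x = 5 and x = 15 mm: boundary at the
  # mid-plane x = 10 mm (voxels left of it -> 1, right -> 2)
  nodes2 <- data.frame(id = 1:4, x = c(5, 5, 15, 15), y = 10, z = c(2, 18, 2, 18),
                       kind = c("root", "endpoint", "root", "endpoint"))
  br2 <- list(
    list(id = 1L, from = 1L, to = 2L, points = cbind(5, 10, seq(2, 18, 1)),
         parent = NA_integer_, generation = 1L),
    list(id = 2L, from = 3L, to = 4L, points = cbind(15, 10, seq(2, 18, 1)),
         parent = NA_integer_, generation = 1L))
  g2 <- centerline_graph(nodes2, br2, 1L)
  t2 <- assign_territories(box, g2, grouping = c("1" = 1L, "2" = 2L))
  lab <- vdata(t2$labels)
  xc <- (seq_len(10) - 0.5) * 2
  for (i in seq_len(10))
    expect_true(all(lab[i, , ] == ifelse(xc[i] < 10, 1L, 2L)),
                info = paste("column", i))
})

test_that("territories are exhaustive, exclusive, and spacing-covariant", {
  ph <- default_phantom()
  terr <- ph$territory_truth
  lab <- vdata(terr$labels)
  inside <- vdata(ph$liver_mask) & !vdata(ph$tumor_mask)
  expect_identical(lab > 0L, inside)   # exhaustive and exclusive by construction
  expect_setequal(unique(lab[inside]), unique(terr$branch_to_territory))

  # isotropic rescaling of spacing and geometry leaves labels unchanged
  g <- ph$centerline_truth
  g2 <- g
  g2$branches <- lapply(g$branches, function(b) { b$points <- b$points * 2; b })
  m1 <- as_volume(array(inside, dim(lab)), vol_spacing(ph$liver_mask))
  m2 <- as_volume(array(inside, dim(lab)), vol_spacing(ph$liver_mask) * 2)
  a1 <- assign_territories(m1, g, grouping = terr$branch_to_territory)
  a2 <- assign_territories(m2, g2, grouping = terr$branch_to_territory,
                           step_mm = 2)
  expect_identical(vdata(a1$labels), vdata(a2$labels))
})

test_that("nearest-branch labels agree with the brute-force oracle", {
  for (seed in c(11, 12, 13)) {
    spec <- small_phantom_spec(seed)
    tree <- make_vessel_tree(spec)
    liver <- sirtpartition:::ellipsoid_mask(spec$grid_shape, spec$voxel_spacing_mm,
                                            spec$liver_center_mm, spec$liver_semiaxes_mm)
    grouping <- group_branches(tree$graph, 2)
    got <- assign_territories(as_volume(liver, spec$voxel_spacing_mm),
                              tree$graph, grouping)
    want <- brute_force_territories(liver, spec$voxel_spacing_mm, tree$graph, grouping)
    expect_identical(vdata(got$labels), want, label = paste("seed", seed))
  }
})

test_that("branch grouping follows subtree structure and explicit maps", {
  ph <- default_phantom()
  g <- ph$centerline_truth
  expect_equal(length(unique(group_branches(g, 1))), 1L)
  expect_equal(length(unique(group_branches(g, 2))), 2L)
  expect_equal(length(unique(group_branches(g, 3))), 4L)

  # depth exceeded: one territory per leaf branch, with warning
  expect_warning(deep <- group_branches(g, 9), "exceeds tree depth")
  gen <- branch_generations(g)
  par <- sirtpartition:::branch_parents(g)
  n_leaves <- sum(!(names(gen) %in% as.character(par[!is.na(par)])))
  expect_equal(length(unique(deep)), n_leaves)

  m <- group_branches(g, map = setNames(c("A", "A", "B", "B", "A", "B", "B"),
                                        as.character(1:7)))
  expect_equal(length(unique(m)), 2L)
  expect_error(group_branches(g, map = c("1" = "A")), "cover every branch")
})

test_that("degenerate vessel inputs are rejected or repaired with warnings", {
  empty <- as_volume(array(FALSE, c(5, 5, 5)), 1)
  expect_error(skeletonize_vessels(empty), "empty")
  two <- array(FALSE, c(9, 9, 9))
  two[2, 2, 2:8] <- TRUE   # 7 voxels
  two[7, 7, 4:6] <- TRUE   # 3 voxels, disconnected
  expect_warning(sk <- skeletonize_vessels(as_volume(two, 1)), "largest")
  expect_equal(sum(sk), 7)
  expect_error(assign_territories(empty, default_phantom()$centerline_truth),
               "empty")
})
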