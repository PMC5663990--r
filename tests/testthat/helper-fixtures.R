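# Shared fixtures and independent oracles, all built in code at test time.

# hand-built partition table (bypasses images) for dosimetry/planning math
make_table <- function(roles, counts, masses) {
  n <- length(roles)
  data.frame(partition = seq_len(n), name = paste0("p", seq_len(n)),
             role = roles, voxels = 1L, volume_mL = masses / 1.05 * 1000,
             mass_kg = masses, counts = counts, f = NA_real_,
             activity_GBq = NA_real_, dose_Gy = NA_real_, empty = FALSE,
             stringsAsFactors = FALSE)
}

# rasterize a capsule (tube segment) into a logical array, spacing 1 mm
rasterize_segment <- function(a, p0, p1, radius) {
  d <- dim(a)
  for (t in seq(0, 1, by = 0.01)) {
    p <- p0 * (1 - t) + p1 * t
    xs <- max(1, floor(p[1] - radius)):min(d[1], ceiling(p[1] + radius))
    ys <- max(1, floor(p[2] - radius)):min(d[2], ceiling(p[2] + radius))
    zs <- max(1, floor(p[3] - radius)):min(d[3], ceiling(p[3] + radius))
    for (x in xs) for (y in ys) for (z in zs)
      if ((x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2 <= radius^2)
        a[x, y, z] <- TRUE
  }
  a
}

# independent brute-force nearest-branch labeling: scan every (voxel,
# polyline-point) pair in R; ties resolved to the lowest branch id by
# ordering points by ascending branch id and taking the first minimum
brute_force_territories <- function(mask, spacing, graph, grouping, step_mm = 1) {
  pts <- list(); ids <- list()
  for (b in graph$branches[order(vapply(graph$branches, `[[`, 0L, "id"))]) {
    p <- b$points
    out <- p[1, , drop = FALSE]
    for (i in 2:nrow(p)) {
      seg <- p[i, ] - p[i - 1, ]
      len <- sqrt(sum(seg^2))
      nseg <- max(1L, ceiling(len / step_mm))
      tt <- seq_len(nseg) / nseg
      out <- rbind(out, cbind(p[i - 1, 1] + tt * seg[1],
                              p[i - 1, 2] + tt * seg[2],
                              p[i - 1, 3] + tt * seg[3]))
    }
    pts[[length(pts) + 1]] <- out
    ids[[length(ids) + 1]] <- rep(b$id, nrow(out))
  }
  pts <- do.call(rbind, pts); ids <- unlist(ids)
  idx <- which(mask, arr.ind = TRUE)
  vox <- sweep(idx - 0.5, 2, spacing, "*")
  lab <- array(0L, dim(mask))
  for (i in seq_len(nrow(vox))) {
    d2 <- (pts[, 1] - vox[i, 1])^2 + (pts[, 2] - vox[i, 2])^2 +
      (pts[, 3] - vox[i, 3])^2
    lab[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      as.integer(grouping[as.character(ids[which.min(d2)])])
  }
  lab
}

# a small phantom spec that fits a <= 32^3 grid (for brute-force oracles)
small_phantom_spec <- function(seed, generations = 3L, tumors = list()) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), voxel_spacing_mm = 4.795,
               liver_center_mm = c(77, 77, 62), liver_semiaxes_mm = c(52, 40, 32),
               lung_box_mm = list(lo = c(30, 30, 110), hi = c(120, 120, 145)),
               vessel_root_mm = c(32, 77, 62), generations = generations,
               segment_length_mm = c(28, 40), vessel_radius_mm = 4,
               tumors = tumors, true_TN = if (length(tumors)) 6 else 1,
               true_lung_shunt = 0.1, total_counts = 5e5, rng_seed = seed)
}

# default full-size phantom, built once and reused across tests
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_phantom(phantom_spec())
    cache
  }
})

vdata <- function(v) sirtpartition:::vol_data(v)
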