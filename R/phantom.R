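#' Synthetic SIRT phantom specification
#'
#' Describes a complete synthetic patient: an ellipsoidal liver, a lung
#' slab, spherical tumors, a procedurally grown arterial tree, a
#' ground-truth activity distribution (uniform normal-liver density,
#' `true_TN` times that density inside tumors, and a lung fraction equal to
#' `true_lung_shunt`), and the SPECT-like imaging chain (Gaussian
#' point-spread blur of `psf_fwhm_mm` FWHM followed by Poisson counting).
#'
#' Defaults emulate the imaging geometry of a clinical MAA SPECT: 4.795-mm
#' isotropic voxels and a 6-mm-FWHM reconstruction point spread. The lung
#' slab is placed well clear of the liver so that blurred counts from one
#' organ cannot reach the other's counting region.
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_spacing_mm voxel spacing (mm), length 1 or 3.
#' @param liver_center_mm,liver_semiaxes_mm liver ellipsoid (mm).
#' @param lung_box_mm lung slab as `list(lo = , hi = )` corner positions (mm).
#' @param vessel_root_mm arterial inlet position (mm); must lie inside the liver.
#' @param generations number of bifurcation generations (1 = single segment).
#' @param branch_angle_deg range of bifurcation half-angles (degrees).
#' @param segment_length_mm range of generation-1 segment lengths (mm).
#' @param length_taper,radius_taper per-generation multiplicative taper.
#' @param vessel_radius_mm generation-1 vessel radius (mm).
#' @param tumors list of `list(center = mm, radius = mm)` spheres, all inside
#'   the liver.
#' @param true_TN ground-truth tumor-to-normal activity concentration ratio (> 0).
#' @param true_lung_shunt ground-truth lung shunt fraction in `[0, 1)`.
#' @param psf_fwhm_mm imaging point-spread FWHM (mm, >= 0).
#' @param total_counts expected total image counts.
#' @param rng_seed integer seed driving tree growth and Poisson sampling.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing_mm = 4.795,
                         liver_center_mm = c(150, 150, 105),
                         liver_semiaxes_mm = c(105, 80, 62),
                         lung_box_mm = list(lo = c(60, 60, 205), hi = c(250, 250, 270)),
                         vessel_root_mm = c(60, 150, 105),
                         generations = 3L,
                         branch_angle_deg = c(25, 50),
                         segment_length_mm = c(45, 75),
                         length_taper = 0.7,
                         radius_taper = 0.75,
                         vessel_radius_mm = 6,
                         tumors = list(list(center = c(195, 175, 115), radius = 20)),
                         true_TN = 6,
                         true_lung_shunt = 0.1,
                         psf_fwhm_mm = 6,
                         total_counts = 2e6,
                         rng_seed = 1L) {
  spacing <- if (length(voxel_spacing_mm) == 1L) rep(voxel_spacing_mm, 3L) else voxel_spacing_mm
  spec <- list(grid_shape = as.integer(grid_shape), voxel_spacing_mm = spacing,
               liver_center_mm = liver_center_mm, liver_semiaxes_mm = liver_semiaxes_mm,
               lung_box_mm = lung_box_mm, vessel_root_mm = vessel_root_mm,
               generations = as.integer(generations),
               branch_angle_deg = branch_angle_deg,
               segment_length_mm = segment_length_mm,
               length_taper = length_taper, radius_taper = radius_taper,
               vessel_radius_mm = vessel_radius_mm, tumors = tumors,
               true_TN = true_TN, true_lung_shunt = true_lung_shunt,
               psf_fwhm_mm = psf_fwhm_mm, total_counts = total_counts,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

ellipsoid_value <- function(p, center, semi) sum(((p - center) / semi)^2)

validate_phantom_spec <- function(spec) {
  if (spec$true_lung_shunt < 0 || spec$true_lung_shunt >= 1)
    stop("true_lung_shunt must lie in [0, 1)", call. = FALSE)
  if (spec$true_TN <= 0) stop("true_TN must be > 0", call. = FALSE)
  if (spec$psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  if (spec$generations < 1L) stop("generations must be >= 1", call. = FALSE)
  if (ellipsoid_value(spec$vessel_root_mm, spec$liver_center_mm, spec$liver_semiaxes_mm) > 1)
    stop("vessel root lies outside the liver", call. = FALSE)
  for (tu in spec$tumors) {
    # sphere-in-ellipsoid (conservative: shrink each semi-axis by the radius)
    if (any(spec$liver_semiaxes_mm <= tu$radius) ||
        ellipsoid_value(tu$center, spec$liver_center_mm,
                        spec$liver_semiaxes_mm - tu$radius) > 1)
      stop("tumor sphere is not inside the liver ellipsoid", call. = FALSE)
  }
  invisible(spec)
}

# evaluate code with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# masks from analytic geometry ------------------------------------------------

voxel_center_grid <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

ellipsoid_mask <- function(shape, spacing, center, semi) {
  g <- voxel_center_grid(shape, spacing)
  fx <- ((g$x - center[1]) / semi[1])^2
  fy <- ((g$y - center[2]) / semi[2])^2
  fz <- ((g$z - center[3]) / semi[3])^2
  array(outer(outer(fx, fy, "+"), fz, "+") <= 1, shape)
}

sphere_mask <- function(shape, spacing, center, radius) {
  ellipsoid_mask(shape, spacing, center, rep(radius, 3))
}

box_mask <- function(shape, spacing, lo, hi) {
  g <- voxel_center_grid(shape, spacing)
  array(outer(outer(g$x >= lo[1] & g$x <= hi[1],
                    g$y >= lo[2] & g$y <= hi[2], "&"),
              g$z >= lo[3] & g$z <= hi[3], "&"), shape)
}

#' Grow the phantom's arterial tree and rasterize it
#'
#' Recursive bifurcation: each branch ends in two children whose directions
#' deviate from the parent by angles drawn from `branch_angle_deg`, with
#' lengths and radii tapered per generation; segments are clipped to stay
#' inside the liver ellipsoid. Deterministic given `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return `list(graph = centerline_graph, vessel_mask = sirt_volume)`. The
#'   graph has `2^generations - 1` branches for a strict bifurcating spec.
#' @export
make_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, grow_tree(spec))
}

grow_tree <- function(spec) {
  center <- spec$liver_center_mm
  semi <- spec$liver_semiaxes_mm
  safety <- 0.92 # keep endpoints off the capsule so children have room

  clip_inside <- function(start, end) {
    # shrink the segment toward start until the endpoint is inside the
    # safety ellipsoid
    for (i in 1:25) {
      if (ellipsoid_value(end, center, semi * safety) <= 1) return(end)
      end <- start + 0.85 * (end - start)
    }
    start + 0.2 * (end - start)
  }
  rand_perp <- function(d) {
    repeat {
      v <- stats::rnorm(3)
      v <- v - sum(v * d) * d
      n <- sqrt(sum(v^2))
      if (n > 1e-8) return(v / n)
    }
  }
  rotate_toward <- function(d, u, theta) {
    # rotate unit vector d by theta toward unit vector u (u orthogonal to d)
    cos(theta) * d + sin(theta) * u
  }

  nodes <- list(); branches <- list()
  add_node <- function(pos, kind) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = length(nodes) + 1L, x = pos[1], y = pos[2], z = pos[3], kind = kind)
    length(nodes)
  }

  root_node <- add_node(spec$vessel_root_mm, "root")
  d0 <- center - spec$vessel_root_mm
  d0 <- d0 / sqrt(sum(d0^2))

  recurse <- function(start, dir, gen, from_node, parent_id) {
    len <- stats::runif(1, spec$segment_length_mm[1], spec$segment_length_mm[2]) *
      spec$length_taper^(gen - 1)
    end <- clip_inside(start, start + len * dir)
    new_dir <- end - start
    nd <- sqrt(sum(new_dir^2))
    dir <- if (nd > 1e-8) new_dir / nd else dir
    kind <- if (gen < spec$generations) "bifurcation" else "endpoint"
    to_node <- add_node(end, kind)
    bid <- length(branches) + 1L
    branches[[bid]] <<- list(
      id = bid, from = from_node, to = to_node,
      points = rbind(start, end), parent = parent_id, generation = gen,
      radius_mm = spec$vessel_radius_mm * spec$radius_taper^(gen - 1))
    if (gen < spec$generations) {
      u <- rand_perp(dir)
      th <- stats::runif(2, spec$branch_angle_deg[1], spec$branch_angle_deg[2]) * pi / 180
      for (s in c(1, -1)) {
        cd <- rotate_toward(dir, s * u, th[(3 - s) / 2])
        recurse(end, cd / sqrt(sum(cd^2)), gen + 1L, to_node, bid)
      }
    }
  }
  recurse(spec$vessel_root_mm, d0, 1L, root_node, NA_integer_)

  node_df <- do.call(rbind, nodes)
  rownames(node_df) <- NULL
  # densify polylines so graph invariants (point spacing) hold on any grid
  step <- min(spec$voxel_spacing_mm)
  branches <- lapply(branches, function(b) {
    b$points <- densify_polyline(b$points, step)
    b
  })
  graph <- centerline_graph(node_df, branches, root_node)

  mask <- rasterize_tree(graph, spec$grid_shape, spec$voxel_spacing_mm)
  list(graph = graph, vessel_mask = as_volume(mask, spec$voxel_spacing_mm))
}

# mark every voxel whose center lies within a branch radius of its polyline
rasterize_tree <- function(graph, shape, spacing) {
  mask <- array(FALSE, shape)
  for (b in graph$branches) {
    r <- max(b$radius_mm, 0.55 * max(spacing)) # always at least one voxel wide
    pts <- densify_polyline(b$points, min(spacing) / 2)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      lo <- pmax(1L, floor((p - r) / spacing + 0.5))
      hi <- pmin(shape, ceiling((p + r) / spacing + 0.5))
      if (any(lo > hi)) next
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      dx2 <- ((xs - 0.5) * spacing[1] - p[1])^2
      dy2 <- ((ys - 0.5) * spacing[2] - p[2])^2
      dz2 <- ((zs - 0.5) * spacing[3] - p[3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
      mask[xs, ys, zs] <- mask[xs, ys, zs] | inside
    }
  }
  mask
}

#' Ground-truth activity distribution
#'
#' Uniform unit density over normal liver, `true_TN` times that density in
#' every tumor voxel, and a uniform lung density scaled so the lung's share
#' of total (lung + liver) activity equals `true_lung_shunt`. The result is
#' a relative uptake density; absolute scale is irrelevant downstream.
#'
#' @param liver_mask,tumor_mask,lung_mask binary [as_volume()] objects on a
#'   common grid (`tumor_mask` must be a subset of `liver_mask`).
#' @param true_TN tumor-to-normal concentration ratio (> 0).
#' @param true_lung_shunt lung activity fraction in `[0, 1)`.
#' @return numeric activity volume.
#' @export
make_activity_truth <- function(liver_mask, tumor_mask, lung_mask,
                                true_TN, true_lung_shunt) {
  check_same_grid(liver_mask, lung_mask, "liver mask", "lung mask")
  check_same_grid(liver_mask, tumor_mask, "liver mask", "tumor mask")
  if (true_TN <= 0) stop("true_TN must be > 0", call. = FALSE)
  if (true_lung_shunt < 0 || true_lung_shunt >= 1)
    stop("true_lung_shunt must lie in [0, 1)", call. = FALSE)
  liv <- as.logical(vol_data(liver_mask))
  tum <- as.logical(vol_data(tumor_mask))
  lun <- as.logical(vol_data(lung_mask))
  if (!any(liv)) stop("liver mask is empty", call. = FALSE)
  if (!any(tum) && true_TN != 1)
    stop("true_TN != 1 requested but the tumor mask is empty", call. = FALSE)
  if (any(tum & !liv)) stop("tumor mask extends outside the liver", call. = FALSE)
  if (any(lun & liv)) stop("lung and liver masks overlap", call. = FALSE)

  act <- array(0, dim(liver_mask))
  act[liv] <- 1
  act[tum] <- true_TN
  liver_total <- sum(act)
  if (true_lung_shunt > 0) {
    if (!any(lun)) stop("lung shunt requested but the lung mask is empty", call. = FALSE)
    lung_total <- liver_total * true_lung_shunt / (1 - true_lung_shunt)
    act[lun] <- lung_total / sum(lun)
  }
  as_volume(act, vol_spacing(liver_mask))
}

#' Simulate a SPECT-like count image
#'
#' Normalizes the activity distribution to `total_counts` expected counts,
#' convolves it with an anisotropy-aware Gaussian point spread of
#' `psf_fwhm_mm` FWHM (zero-padded, mass-conserving away from the grid
#' boundary) and draws independent Poisson counts per voxel.
#'
#' @param activity_truth numeric [as_volume()] of relative uptake density.
#' @param psf_fwhm_mm point-spread FWHM in mm (0 = no blur).
#' @param total_counts expected total counts (> 0).
#' @param seed integer seed for the Poisson draw.
#' @param poisson set `FALSE` to return the noiseless expected counts.
#' @return count volume (expected counts when `poisson = FALSE`).
#' @export
simulate_spect <- function(activity_truth, psf_fwhm_mm = 6, total_counts,
                           seed = 1L, poisson = TRUE) {
  if (total_counts <= 0) stop("total_counts must be > 0", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  a <- vol_data(activity_truth)
  s <- sum(a)
  if (s <= 0) stop("activity distribution is empty", call. = FALSE)
  lam <- as_volume(a * (total_counts / s), vol_spacing(activity_truth))
  lam <- gaussian_blur(lam, psf_fwhm_mm)
  if (!poisson) return(lam)
  counts <- with_seed(seed, rpois(length(lam), as.vector(vol_data(lam))))
  as_volume(array(as.numeric(counts), dim(lam)), vol_spacing(activity_truth))
}

#' Generate a complete phantom bundle
#'
#' Runs the whole generator: organ masks, arterial tree and vessel mask,
#' ground-truth territory labels (nearest-branch assignment on the true
#' tree, grouped at `territory_generation`), ground-truth activity, and the
#' simulated count image.
#'
#' @param spec a [phantom_spec()].
#' @param territory_generation subtree generation for the ground-truth
#'   territory grouping (see [group_branches()]).
#' @param poisson draw Poisson counts (default) or keep the noiseless image.
#' @return object of class `sirt_phantom`: list with `spec`, `liver_mask`,
#'   `lung_mask`, `tumor_mask` (union), `tumor_masks` (per sphere),
#'   `vessel_mask`, `centerline_truth`, `territory_truth`,
#'   `activity_truth`, `count_image`.
#' @export
build_phantom <- function(spec, territory_generation = 2L, poisson = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape; spacing <- spec$voxel_spacing_mm
  liver <- ellipsoid_mask(shape, spacing, spec$liver_center_mm, spec$liver_semiaxes_mm)
  lung <- box_mask(shape, spacing, spec$lung_box_mm$lo, spec$lung_box_mm$hi)
  lung <- lung & !liver
  tumor_masks <- lapply(spec$tumors, function(tu)
    as_volume(sphere_mask(shape, spacing, tu$center, tu$radius) & liver, spacing))
  tumor <- array(FALSE, shape)
  for (tm in tumor_masks) tumor <- tumor | vol_data(tm)

  tree <- make_vessel_tree(spec)
  gmax <- max(branch_generations(tree$graph), na.rm = TRUE)
  grouping <- group_branches(tree$graph, generation = min(territory_generation, gmax))
  territory_truth <- assign_territories(as_volume(liver & !tumor, spacing),
                                        tree$graph, grouping)

  activity <- make_activity_truth(as_volume(liver, spacing),
                                  as_volume(tumor, spacing),
                                  as_volume(lung, spacing),
                                  spec$true_TN, spec$true_lung_shunt)
  counts <- simulate_spect(activity, spec$psf_fwhm_mm, spec$total_counts,
                           seed = spec$rng_seed, poisson = poisson)
  structure(list(spec = spec,
                 liver_mask = as_volume(liver, spacing),
                 lung_mask = as_volume(lung, spacing),
                 tumor_mask = as_volume(tumor, spacing),
                 tumor_masks = tumor_masks,
                 vessel_mask = tree$vessel_mask,
                 centerline_truth = tree$graph,
                 territory_truth = territory_truth,
                 activity_truth = activity,
                 count_image = counts),
            class = "sirt_phantom")
}

#' @export
print.sirt_phantom <- function(x, ...) {
  cat(sprintf(paste0("<sirt_phantom> grid %s, %d tumor(s), %d territories, ",
                     "T/N %.3g, lung shunt %.3g\n"),
              paste(x$spec$grid_shape, collapse = "x"), length(x$tumor_masks),
              length(x$territory_truth$names), x$spec$true_TN,
              x$spec$true_lung_shunt))
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Volumes as NIfTI-1, ground-truth scalars and the generating parameters
#' as a JSON sidecar.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$liver_mask, file.path(dir, "liver.nii.gz"))
  write_volume(phantom$lung_mask, file.path(dir, "lung.nii.gz"))
  write_volume(phantom$tumor_mask, file.path(dir, "tumor.nii.gz"))
  write_volume(phantom$vessel_mask, file.path(dir, "vessels.nii.gz"))
  write_volume(phantom$territory_truth$labels, file.path(dir, "territory_truth.nii.gz"))
  write_volume(phantom$count_image, file.path(dir, "counts.nii.gz"))
  meta <- phantom$spec
  class(meta) <- NULL
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
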