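#' Skeletonize a binary vessel mask
#'
#' Topology-preserving sequential 3-D thinning with six directional
#' subiterations: border voxels are removed only when they are simple
#' points under (26,6) digital topology, and curve endpoints are retained.
#' The result is a single-voxel-wide centerline contained in the mask with
#' the same number of connected components.
#'
#' If the mask has more than one 26-connected component, only the largest
#' is skeletonized, with a warning (an arterial tree should be connected).
#'
#' @param vessel_mask binary [as_volume()].
#' @param spacing_mm voxel spacing (defaults to the volume's).
#' @return logical skeleton volume on the same grid.
#' @export
skeletonize_vessels <- function(vessel_mask, spacing_mm = NULL) {
  spacing <- spacing_or(vessel_mask, spacing_mm)
  check_binary(vessel_mask, "vessel mask")
  m <- array(as.logical(vol_data(vessel_mask)), dim(vessel_mask))
  if (!any(m)) stop("vessel mask is empty", call. = FALSE)
  comp <- cpp_label26(m, dim(m))
  k <- max(comp)
  if (k > 1L) {
    warning(sprintf("vessel mask has %d connected components; using the largest", k),
            call. = FALSE)
    sizes <- tabulate(comp[comp > 0L], nbins = k)
    m <- array(comp == which.max(sizes), dim(m))
  }
  sk <- cpp_thin3d(m, dim(m))
  as_volume(array(as.logical(sk), dim(m)), spacing)
}

#' Territory label map
#'
#' The result of [assign_territories()]: an integer label volume
#' (0 = outside the liver, k >= 1 = territory), the branch-to-territory
#' mapping and territory names.
#'
#' @param labels integer [as_volume()].
#' @param branch_to_territory named integer vector (branch id -> territory).
#' @param names character territory names.
#' @return object of class `territory_map`.
#' @export
territory_map <- function(labels, branch_to_territory, names = NULL) {
  k <- length(unique(branch_to_territory))
  if (is.null(names)) names <- paste0("territory_", seq_len(k))
  structure(list(labels = labels, branch_to_territory = branch_to_territory,
                 names = names),
            class = "territory_map")
}

#' @export
print.territory_map <- function(x, ...) {
  cat(sprintf("<territory_map> %d territories over %d liver voxels\n",
              length(x$names), sum(vol_data(x$labels) > 0)))
  invisible(x)
}

#' Assign liver voxels to arterial territories
#'
#' Every liver voxel is assigned to the branch whose centerline polyline is
#' nearest in physical (mm, anisotropy-aware) Euclidean distance; the
#' branch's territory under `grouping` becomes the voxel label. Polylines
#' are densified to at most `step_mm` between vertices so the point-to-line
#' discretisation error stays below voxel size. Ties go to the lowest
#' branch id, making labels deterministic.
#'
#' @param liver_mask binary [as_volume()] of the region to label (typically
#'   liver minus tumors).
#' @param graph a [centerline_graph()].
#' @param grouping branch-to-territory map from [group_branches()]; default
#'   groups by generation-2 subtrees.
#' @param spacing_mm voxel spacing (defaults to the mask's).
#' @param step_mm polyline densification step in mm.
#' @return a [territory_map()]; labels are exhaustive and mutually
#'   exclusive over `liver_mask`.
#' @export
assign_territories <- function(liver_mask, graph, grouping = NULL,
                               spacing_mm = NULL, step_mm = 1) {
  spacing <- spacing_or(liver_mask, spacing_mm)
  check_binary(liver_mask, "liver mask")
  m <- as.logical(vol_data(liver_mask))
  if (!any(m)) stop("liver mask is empty", call. = FALSE)
  if (length(graph$branches) == 0) stop("centerline graph has no branches", call. = FALSE)
  if (is.null(grouping)) {
    gmax <- max(branch_generations(graph), na.rm = TRUE)
    grouping <- group_branches(graph, generation = min(2L, gmax))
  }
  ids <- sort(branch_ids(graph))
  if (!all(as.character(ids) %in% names(grouping)))
    stop("grouping must cover every branch id", call. = FALSE)

  gp <- graph_points(graph, step_mm = step_mm)
  vox <- mask_coords_mm(array(m, dim(liver_mask)), spacing)
  nearest_branch <- cpp_nearest_point_id(vox, gp$points, as.integer(gp$branch))

  lab <- array(0L, dim(liver_mask))
  lab[m] <- as.integer(grouping[as.character(nearest_branch)])
  territory_map(as_volume(lab, spacing), grouping)
}
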