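#' Tumor-margin policy
#'
#' SIRT dosimetry excludes a shell around each tumor from the normal-liver
#' partitions: beta particles emitted at the tumor rim deposit dose up to
#' the maximum Y-90 range of about 11 mm, and imaging blur spills tumor
#' counts into the same shell, so counts found there are not evidence of
#' normal-liver uptake. `disposition` controls where the shell's counts are
#' booked: as their own `excluded_margin` partition (default; they stay in
#' the liver-side activity balance but feed no normal-liver or tumor dose),
#' merged into the nearest tumor partition, or dropped from all partitions.
#'
#' @param margin_mm margin width in mm (default the 11-mm maximum Y-90
#'   emission range; 0 disables the margin).
#' @param disposition one of `"excluded_partition"`, `"merge_into_tumor"`,
#'   `"drop"`.
#' @return object of class `margin_policy`.
#' @export
margin_policy <- function(margin_mm = 11,
                          disposition = c("excluded_partition", "merge_into_tumor", "drop")) {
  if (margin_mm < 0) stop("margin_mm must be >= 0", call. = FALSE)
  structure(list(margin_mm = margin_mm, disposition = match.arg(disposition)),
            class = "margin_policy")
}

#' Voxels within a margin of any tumor
#'
#' The set of liver voxels whose center lies within `margin_mm` (world-mm
#' Euclidean distance, anisotropy-aware) of a tumor voxel center, excluding
#' the tumors themselves.
#'
#' @param tumor_mask,liver_mask binary [as_volume()] on a common grid.
#' @param margin_mm margin width in mm; 0 gives an empty mask.
#' @param spacing_mm voxel spacing (defaults to the mask's).
#' @return logical margin volume.
#' @export
tumor_margin <- function(tumor_mask, liver_mask, margin_mm, spacing_mm = NULL) {
  spacing <- spacing_or(liver_mask, spacing_mm)
  check_same_grid(tumor_mask, liver_mask, "tumor mask", "liver mask")
  if (margin_mm < 0) stop("margin_mm must be >= 0", call. = FALSE)
  tum <- as.logical(vol_data(tumor_mask))
  liv <- as.logical(vol_data(liver_mask))
  if (margin_mm == 0 || !any(tum))
    return(as_volume(array(FALSE, dim(liver_mask)), spacing))
  d <- vol_data(distance_to_mask(as_volume(array(tum, dim(liver_mask)), spacing)))
  margin <- d <= margin_mm & liv & !tum
  if (any(liv & !tum) && all(margin[liv & !tum]))
    stop("margin consumes the entire normal liver; no normal-liver partition left",
         call. = FALSE)
  as_volume(array(margin, dim(liver_mask)), spacing)
}

#' Partition table from a count image
#'
#' Sums image counts over every partition: one lung row, one row per
#' normal-liver territory, one row per 26-connected tumor component, and
#' (under the default margin disposition) one `excluded_margin` row holding
#' the counts inside the tumor margin. Volumes and masses come from voxel
#' counts, voxel volume and a uniform tissue density.
#'
#' With `capture_mm > 0`, background voxels within that distance of a
#' partition contribute their counts to the nearest partition. This mirrors
#' the generous organ regions drawn in clinical shunt quantification and
#' recovers counts the point spread pushed just outside an organ mask;
#' masses always come from the anatomical masks alone.
#'
#' @param count_image numeric [as_volume()] of counts.
#' @param territories a [territory_map()] (or integer label volume) of
#'   normal-liver territories, excluding tumors.
#' @param tumor_mask binary tumor volume (union of all tumors).
#' @param lung_mask binary lung volume.
#' @param margin a [margin_policy()].
#' @param density_kg_per_L tissue density for mass conversion (default 1.05).
#' @param capture_mm background count capture distance in mm (default 0).
#' @return a `partition_table` data.frame with columns `partition`, `name`,
#'   `role`, `voxels`, `volume_mL`, `mass_kg`, `counts`, `f`,
#'   `activity_GBq`, `dose_Gy`, `empty`; attributes carry the label map,
#'   total and background counts, spacing and the margin policy.
#' @export
partition_counts <- function(count_image, territories, tumor_mask, lung_mask,
                             margin = margin_policy(),
                             density_kg_per_L = 1.05, capture_mm = 0) {
  stopifnot(inherits(margin, "margin_policy"))
  if (density_kg_per_L <= 0) stop("density must be > 0", call. = FALSE)
  labels <- if (inherits(territories, "territory_map")) territories$labels else territories
  spacing <- vol_spacing(count_image)
  check_same_grid(count_image, labels, "count image", "territory labels")
  check_same_grid(count_image, tumor_mask, "count image", "tumor mask")
  check_same_grid(count_image, lung_mask, "count image", "lung mask")
  lab <- vol_data(labels)
  tum <- array(as.logical(vol_data(tumor_mask)), dim(tumor_mask))
  lun <- array(as.logical(vol_data(lung_mask)), dim(lung_mask))
  cts <- vol_data(count_image)
  if (any(cts < 0)) stop("count image has negative values", call. = FALSE)
  K <- max(lab)
  if (K < 1) stop("territory label map is empty", call. = FALSE)
  lab[tum] <- 0L # territories never overlap tumors

  # tumor components (26-connectivity), one partition each
  tcomp <- vol_data(label_components(as_volume(tum, spacing)))
  n_tum <- max(tcomp)

  liver_region <- lab > 0L | tum
  code <- array(0L, dim(count_image))
  code[lab > 0L] <- lab[lab > 0L]
  code[tum] <- K + tcomp[tum]
  margin_code <- K + n_tum + 1L
  lung_code <- K + n_tum + 2L

  if (margin$margin_mm > 0 && n_tum > 0) {
    mg <- vol_data(tumor_margin(as_volume(tum, spacing),
                                as_volume(liver_region, spacing),
                                margin$margin_mm, spacing))
    if (margin$disposition == "excluded_partition") {
      code[mg] <- margin_code
    } else if (margin$disposition == "merge_into_tumor") {
      # each margin voxel joins its nearest tumor component
      dmat <- vapply(seq_len(n_tum), function(t)
        as.vector(vol_data(distance_to_mask(as_volume(tcomp == t, spacing)))),
        numeric(length(code)))
      nearest <- max.col(-dmat, ties.method = "first")
      code[mg] <- K + nearest[which(as.vector(mg))]
    } else { # drop
      code[mg] <- 0L
    }
  } else {
    mg <- array(FALSE, dim(count_image))
  }
  code[lun] <- lung_code
  if (!any(code >= 1L & code <= K))
    stop("margin consumes the entire normal liver; no normal-liver partition left",
         call. = FALSE)

  counting_code <- code
  if (capture_mm > 0) {
    counting_code <- capture_background(code, spacing, capture_mm, lung_code)
  }

  sum_counts <- function(cc) {
    out <- numeric(lung_code)
    agg <- tapply(cts[cc > 0L], cc[cc > 0L], sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  counts <- sum_counts(counting_code)
  voxels <- tabulate(code[code > 0L], nbins = lung_code)
  vox_mL <- prod(spacing) / 1000

  ids <- seq_len(lung_code)
  role <- c(rep("normal_liver_territory", K), rep("tumor", n_tum),
            "excluded_margin", "lung")
  name <- c(territory_names(territories, K),
            if (n_tum > 0) paste0("tumor_", seq_len(n_tum)) else character(0),
    "margin", "lung")
  # mass in kg: volume_mL (= cm^3) * density (kg/L) / 1000 mL/L
  tab <- data.frame(partition = ids, name = name, role = role,
                    voxels = voxels, volume_mL = voxels * vox_mL,
                    mass_kg = voxels * vox_mL * density_kg_per_L / 1000,
                    counts = counts, f = NA_real_, activity_GBq = NA_real_,
                    dose_Gy = NA_real_, empty = voxels == 0L,
                    stringsAsFactors = FALSE)
  # drop the margin row when no margin voxels exist or counts were dropped
  if (margin$disposition != "excluded_partition" || !any(mg))
    tab <- tab[tab$role != "excluded_margin", ]
  class(tab) <- c("partition_table", class(tab))
  attr(tab, "label_map") <- as_volume(code, spacing)
  attr(tab, "total_counts") <- sum(cts)
  attr(tab, "background_counts") <- sum(cts) - sum(tab$counts)
  attr(tab, "spacing") <- spacing
  attr(tab, "margin") <- margin
  attr(tab, "density_kg_per_L") <- density_kg_per_L
  tab
}

territory_names <- function(territories, K) {
  if (inherits(territories, "territory_map") &&
      length(territories$names) == K) territories$names
  else paste0("territory_", seq_len(K))
}

# assign background voxels within capture_mm of a partition to the nearest
# partition (argmin over per-partition distance transforms)
capture_background <- function(code, spacing, capture_mm, max_code) {
  dims <- dim(code)
  best <- array(Inf, dims)
  owner <- array(0L, dims)
  for (cc in seq_len(max_code)) {
    if (!any(code == cc)) next
    d <- vol_data(distance_to_mask(as_volume(code == cc, spacing)))
    upd <- d < best
    best[upd] <- d[upd]
    owner[upd] <- cc
  }
  out <- code
  bg <- code == 0L & best <= capture_mm
  out[bg] <- owner[bg]
  out
}

liver_side_roles <- c("normal_liver_territory", "tumor", "excluded_margin")

#' Lung shunt fraction from a partition table
#'
#' The fraction of total counts found in the lungs,
#' `L = c_L / (c_L + c_NL + c_T)`, with all liver-side partitions
#' (normal-liver territories, tumors and any margin partition) in the
#' denominator.
#'
#' @param table a [partition_counts()] table.
#' @return lung shunt fraction in `[0, 1]`.
#' @export
lung_shunt_fraction <- function(table) {
  c_lung <- sum(table$counts[table$role == "lung"])
  c_liver <- sum(table$counts[table$role %in% liver_side_roles])
  if (c_lung + c_liver <= 0) stop("no counts in lung or liver", call. = FALSE)
  c_lung / (c_lung + c_liver)
}

#' Tumor-to-normal activity concentration ratio
#'
#' `T/N = (c_T / m_T) / (c_NL / m_NL)` with counts as activity surrogates,
#' aggregated over all tumor partitions and all normal-liver territories
#' (margin counts belong to neither side).
#'
#' @param table a [partition_counts()] table.
#' @return the T/N ratio.
#' @export
tn_ratio <- function(table) {
  tum <- table[table$role == "tumor", ]
  nl <- table[table$role == "normal_liver_territory", ]
  m_t <- sum(tum$mass_kg); m_nl <- sum(nl$mass_kg)
  c_t <- sum(tum$counts); c_nl <- sum(nl$counts)
  if (m_t <= 0) stop("tumor mass is zero; T/N undefined", call. = FALSE)
  if (m_nl <= 0) stop("normal-liver mass is zero; T/N undefined", call. = FALSE)
  if (c_nl <= 0) stop("normal-liver counts are zero; T/N undefined", call. = FALSE)
  (c_t / m_t) / (c_nl / m_nl)
}

#' Per-label volumes and masses
#'
#' @param labels integer label [as_volume()] (0 = background).
#' @param density_kg_per_L tissue density.
#' @param spacing_mm voxel spacing (defaults to the volume's).
#' @return data.frame with `label`, `voxels`, `volume_mL`, `mass_kg`.
#' @export
partition_masses <- function(labels, density_kg_per_L = 1.05, spacing_mm = NULL) {
  if (density_kg_per_L <= 0) stop("density must be > 0", call. = FALSE)
  spacing <- spacing_or(labels, spacing_mm)
  lab <- vol_data(labels)
  k <- max(lab)
  voxels <- tabulate(lab[lab > 0L], nbins = k)
  vol_mL <- voxels * prod(spacing) / 1000
  data.frame(label = seq_len(k), voxels = voxels, volume_mL = vol_mL,
             mass_kg = vol_mL * density_kg_per_L / 1000,
             empty = voxels == 0L)
}
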