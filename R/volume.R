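#' 3-D volume with physical voxel spacing
#'
#' A minimal container for image volumes: a numeric, integer or logical 3-D
#' array plus the voxel spacing in millimetres along each axis. Used for
#' count images, binary organ masks, territory label maps and dose maps.
#' World coordinates place the center of voxel `(1,1,1)` at
#' `spacing / 2`, i.e. the volume occupies the box from the origin to
#' `dim * spacing` mm.
#'
#' @param data 3-D array (numeric, integer or logical).
#' @param spacing_mm voxel spacing in mm, length 1 (isotropic) or 3.
#' @return An object of class `sirt_volume`: the array with a `spacing`
#'   attribute.
#' @examples
#' v <- as_volume(array(0, c(8, 8, 8)), 4.795)
#' voxel_volume_mL(v)
#' @export
as_volume <- function(data, spacing_mm) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 1 or 3 positive numbers", call. = FALSE)
  structure(data, spacing = spacing_mm, class = "sirt_volume")
}

#' @export
print.sirt_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<sirt_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, %s\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3], typeof(x)))
  invisible(x)
}

#' @rdname as_volume
#' @param x object to test or query.
#' @export
is_volume <- function(x) inherits(x, "sirt_volume")

#' @rdname as_volume
#' @export
vol_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object has no voxel spacing", call. = FALSE)
  sp
}

#' @rdname as_volume
#' @export
voxel_volume_mL <- function(x) prod(vol_spacing(x)) / 1000

# strip class/attrs for raw array math
vol_data <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  a
}

# world-coordinate (mm) of voxel centers for the voxels where mask is TRUE;
# returns an n x 3 matrix
mask_coords_mm <- function(mask, spacing) {
  m <- array(as.logical(vol_data(mask)), dim(mask))
  idx <- which(m, arr.ind = TRUE)
  sweep(idx - 0.5, 2, spacing, "*")
}

check_same_grid <- function(a, b, what_a = "volume A", what_b = "volume B") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s grid %s does not match %s grid %s", what_a,
                 paste(dim(a), collapse = "x"), what_b,
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

check_binary <- function(mask, what = "mask") {
  v <- as.vector(vol_data(mask))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop(sprintf("%s must be binary", what), call. = FALSE)
  invisible(TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Round-trips the voxel data and spacing through the NIfTI-1 format via
#' \pkg{RNifti}. Integer-valued label volumes are written with an integer
#' datatype so labels survive the round-trip exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [as_volume()] object.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  as_volume(array(as.vector(img), dim = dim(img)[1:3]), sp)
}

#' @rdname read_volume
#' @param vol a [as_volume()] object.
#' @export
write_volume <- function(vol, path) {
  a <- vol_data(vol)
  datatype <- "auto"
  if (is.logical(a) || (is.numeric(a) && all(a == round(a)) && max(abs(a)) < 2^31)) {
    a <- array(as.integer(a), dim = dim(a))
    datatype <- "int32"
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- vol_spacing(vol)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
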