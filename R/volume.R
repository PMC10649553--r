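#' CT volume container
#'
#' A `ct_volume` is an ordered stack of transverse slices stored as a 3-D
#' integer array in `(row, col, slice)` order (column-major, 1-based, the
#' native R convention), together with the voxel spacing in millimetres and
#' the intensity scale. Two scales are supported: `"8bit"` (values in
#' 0--255, the scale calcium scoring operates on) and `"HU"` (Hounsfield
#' units, unbounded; convert with [hu_to_8bit()] before scoring).
#'
#' @param voxels 3-D numeric array `(row, col, slice)`; a 2-D matrix is
#'   promoted to a single-slice volume.
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   all strictly positive.
#' @param intensity_scale `"8bit"` or `"HU"`.
#' @param patient_id optional identifier carried through reports.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0L, c(8, 8, 4)), spacing = c(1, 1, 1))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1),
                      intensity_scale = c("8bit", "HU"),
                      patient_id = NA_character_) {
  intensity_scale <- match.arg(intensity_scale)
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a (row, col, slice) array", call. = FALSE)
  voxels <- array(as.vector(voxels), dim(voxels))  # drop foreign classes/attrs
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive lengths (mm)", call. = FALSE)
  if (intensity_scale == "8bit" &&
      (min(voxels) < 0L || max(voxels) > 255L))
    stop("8bit volume has values outside [0, 255]", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing,
         intensity_scale = intensity_scale,
         patient_id = as.character(patient_id)),
    class = "ct_volume"
  )
}

#' Binary segmentation mask
#'
#' Per-voxel vessel membership, geometry-locked to its parent volume: same
#' array shape, same spacing. Used both for ground-truth annotation and for
#' model predictions (1 = vascular system, 0 = everything else).
#'
#' @param voxels 3-D array with values in `{0, 1}`; a matrix is promoted to
#'   one slice.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a (row, col, slice) array", call. = FALSE)
  voxels <- array(as.vector(voxels), dim(voxels))
  storage.mode(voxels) <- "integer"
  if (!all(voxels == 0L | voxels == 1L))
    stop("mask values must all be 0 or 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive lengths (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing), class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d slices, %s scale, spacing %s mm, patient %s\n",
              d[1], d[2], d[3], x$intensity_scale,
              paste(signif(x$spacing, 3), collapse = "x"), x$patient_id))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d slices, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# Shared geometry check used by scoring and metrics.
check_same_geometry <- function(a, b) {
  da <- dim(a$voxels); db <- dim(b$voxels)
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

voxel_volume_mm3 <- function(spacing) prod(spacing)
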