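#' Read a CT volume from disk
#'
#' Supported containers:
#' * a NIfTI file (`.nii` / `.nii.gz`); spacing is taken from the header
#'   `pixdim`,
#' * a directory of per-slice 8-bit grayscale PNGs, stacked in lexical
#'   filename order, with a required `volume.json` sidecar carrying
#'   `spacing` (and optionally `intensity_scale`, `patient_id`).
#'
#' @param path file or directory path.
#' @param intensity_scale scale to stamp on the result when the container
#'   does not carry one (NIfTI files written by [write_volume()] store it
#'   in a sidecar when the scale is `"HU"`; PNG stacks are always 8-bit).
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, intensity_scale = NULL) {
  if (dir.exists(path)) return(read_png_stack(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  meta <- sidecar_path(path)
  scale <- intensity_scale
  pid <- NA_character_
  if (file.exists(meta)) {
    side <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (is.null(scale)) scale <- side$intensity_scale
    if (!is.null(side$patient_id)) pid <- side$patient_id
  }
  if (is.null(scale)) scale <- if (min(vox) >= 0 && max(vox) <= 255) "8bit" else "HU"
  ct_volume(round(vox), spacing = RNifti::pixdim(img)[1:3],
            intensity_scale = scale, patient_id = pid)
}

#' Write a CT volume to disk
#'
#' Writes NIfTI when `path` ends in `.nii`/`.nii.gz` (with a JSON sidecar
#' recording the intensity scale and patient id), otherwise treats `path`
#' as a directory and writes one 8-bit grayscale PNG per slice
#' (`slice_001.png`, ...) plus a `volume.json` sidecar with the spacing.
#' Round-trip `write_volume()` then [read_volume()] is voxel-identical and
#' spacing-preserving.
#'
#' @param vol a [ct_volume()].
#' @param path output file (`.nii`, `.nii.gz`) or directory.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    dtype <- if (vol$intensity_scale == "8bit") "uint8" else "int32"
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path, datatype = dtype)
    jsonlite::write_json(
      list(intensity_scale = vol$intensity_scale, patient_id = vol$patient_id,
           spacing = vol$spacing),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    write_png_stack(vol, path)
  }
  invisible(path)
}

#' @rdname read_volume
#' @param mask_path path of a mask written by [write_mask()].
#' @param spacing spacing override for `read_mask` when no sidecar exists.
#' @export
read_mask <- function(mask_path, spacing = NULL) {
  v <- read_volume(mask_path, intensity_scale = "8bit")
  if (!is.null(spacing)) v$spacing <- as.numeric(spacing)
  binary_mask(v$voxels, spacing = v$spacing)
}

#' @rdname write_volume
#' @param mask a [binary_mask()]; stored as unsigned 8-bit with values {0, 1}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_volume(ct_volume(mask$voxels, spacing = mask$spacing,
                         intensity_scale = "8bit"), path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

read_png_stack <- function(dir) {
  meta_file <- file.path(dir, "volume.json")
  if (!file.exists(meta_file))
    stop("PNG stack requires a volume.json sidecar with `spacing`", call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG slices in ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # grayscale written as such; guard
    round(m * 255)
  })
  shp <- dim(slices[[1L]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stop("mixed slice shapes in PNG stack", call. = FALSE)
  vox <- array(unlist(slices), c(shp, length(slices)))
  ct_volume(vox, spacing = meta$spacing, intensity_scale = "8bit",
            patient_id = if (is.null(meta$patient_id)) NA_character_ else meta$patient_id)
}

write_png_stack <- function(vol, dir) {
  if (vol$intensity_scale != "8bit")
    stop("PNG stacks are 8-bit; convert with hu_to_8bit() first", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(vol$voxels)[3L]
  for (s in seq_len(n)) {
    png::writePNG(vol$voxels[, , s] / 255,
                  file.path(dir, sprintf("slice_%03d.png", s)))
  }
  jsonlite::write_json(
    list(spacing = vol$spacing, patient_id = vol$patient_id,
         intensity_scale = "8bit", n_slices = n),
    file.path(dir, "volume.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Convert a Hounsfield-unit volume to the 8-bit scale
#'
#' Linear map of the window `[lo, hi]` onto `[0, 255]`, clipping outside the
#' window and rounding half up to the nearest integer. The default window is
#' the volume's own min--max (the common whole-range 8-bit conversion);
#' a fixed window can be supplied for cross-patient comparability. The map
#' is monotone non-decreasing in input intensity for every window. A
#' degenerate window (constant volume under the default) maps everything
#' to 0 by convention.
#'
#' @param vol a [ct_volume()] on the `"HU"` scale.
#' @param window optional `c(lo, hi)` with `lo < hi`.
#' @return A [ct_volume()] on the `"8bit"` scale.
#' @examples
#' v <- ct_volume(array(c(-1000, 0, 1000), c(1, 1, 3)), intensity_scale = "HU")
#' as.vector(hu_to_8bit(v, window = c(-1000, 1000))$voxels)  # 0 128 255
#' @export
hu_to_8bit <- function(vol, window = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_scale != "HU")
    stop("`vol` must be on the HU scale", call. = FALSE)
  x <- vol$voxels
  if (is.null(window)) window <- range(x)
  lo <- window[1L]; hi <- window[2L]
  if (lo > hi) stop("window lo must not exceed hi", call. = FALSE)
  if (lo == hi) {
    y <- array(0L, dim(x))
  } else {
    y <- floor(pmin(pmax((x - lo) / (hi - lo), 0), 1) * 255 + 0.5)  # round half up
  }
  ct_volume(y, spacing = vol$spacing, intensity_scale = "8bit",
            patient_id = vol$patient_id)
}
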