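#' CT volume container
#'
#' A minimal container for a 3D CT raster: a numeric array of Hounsfield
#' units plus voxel spacing and world origin. All feature and preprocessing
#' functions in this package consume and return `ct_volume` objects.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing_mm Positive numeric length-3 voxel spacing (mm), x/y/z.
#' @param origin Numeric length-3 world origin (mm). Default `c(0, 0, 0)`.
#' @return An object of class `ct_volume` with elements `values`,
#'   `spacing_mm`, `origin`.
#' @examples
#' v <- ct_volume(array(-800, c(8, 8, 8)), spacing_mm = c(1, 1, 1))
#' dim(v$values)
#' @export
ct_volume <- function(values, spacing_mm, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

check_mask <- function(vol, mask, require_nonempty = TRUE) {
  if (!is.logical(mask) || !identical(dim(mask), dim(vol$values)))
    stop("mask must be a logical array congruent with the volume")
  if (require_nonempty && !any(mask))
    stop("mask is empty")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti that carry voxel spacing through the NIfTI
#' header. Masks are stored as 0/1 volumes.
#'
#' @param vol A [ct_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a [ct_volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim(img)[1:3]),
            spacing_mm = RNifti::pixdim(img)[1:3])
}
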