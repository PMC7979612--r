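#' Lung masking by Hounsfield-unit window
#'
#' Thresholds the volume to the parenchymal HU window and keeps only the
#' largest 26-connected component, mimicking the manual cleanup used when
#' lungs are segmented semi-automatically (hilar vessels and unconnected
#' windowed voxels fall outside the retained component).
#'
#' @param vol A [ct_volume()].
#' @param hu_low,hu_high Inclusive HU window bounds. Defaults −950 / −150,
#'   the standard lung parenchyma window.
#' @param largest_component Keep only the largest 26-connected component
#'   (default `TRUE`).
#' @return Logical 3D array congruent with `vol$values`.
#' @export
mask_lung <- function(vol, hu_low = -950, hu_high = -150,
                      largest_component = TRUE) {
  stopifnot(inherits(vol, "ct_volume"), hu_low <= hu_high)
  m <- vol$values >= hu_low & vol$values <= hu_high
  if (!any(m)) stop("empty mask: no voxels inside the HU window")
  if (largest_component) m <- largest_component_26(m)
  if (!any(m)) stop("empty mask after component filtering")
  m
}

#' Resample a volume (and mask) to isotropic spacing
#'
#' Trilinear interpolation for HU values, nearest-neighbour for the mask so
#' it stays binary. The output grid covers the same physical extent as the
#' input (to within one voxel) at spacing `target_mm` in all axes.
#'
#' @param vol A [ct_volume()].
#' @param mask Optional logical array congruent with `vol$values`.
#' @param target_mm Target isotropic spacing in mm (default 2).
#' @return If `mask` is supplied, `list(volume =, mask =)`; otherwise the
#'   resampled [ct_volume()].
#' @export
resample_isotropic <- function(vol, mask = NULL, target_mm = 2) {
  stopifnot(inherits(vol, "ct_volume"), target_mm > 0)
  if (!is.null(mask)) check_mask(vol, mask, require_nonempty = FALSE)
  d <- dim(vol$values)
  sp <- vol$spacing_mm
  d_out <- pmax(1L, floor((d - 1L) * sp / target_mm) + 1L)
  if (any(d_out < 2L))
    stop("resampled grid smaller than 2 voxels per axis")
  # sample coordinates in source index space (1-based)
  gx <- (seq_len(d_out[1]) - 1) * target_mm / sp[1] + 1
  gy <- (seq_len(d_out[2]) - 1) * target_mm / sp[2] + 1
  gz <- (seq_len(d_out[3]) - 1) * target_mm / sp[3] + 1
  out <- trilinear_gather(vol$values, gx, gy, gz)
  res_vol <- ct_volume(out, spacing_mm = rep(target_mm, 3), origin = vol$origin)
  if (is.null(mask)) return(res_vol)
  rx <- pmin(pmax(round(gx), 1L), d[1])
  ry <- pmin(pmax(round(gy), 1L), d[2])
  rz <- pmin(pmax(round(gz), 1L), d[3])
  res_mask <- mask[rx, ry, rz, drop = FALSE]
  dim(res_mask) <- d_out
  list(volume = res_vol, mask = res_mask)
}

# Vectorized trilinear interpolation of V at the grid gx x gy x gz
# (coordinates in 1-based source index space, clamped to the array).
trilinear_gather <- function(V, gx, gy, gz) {
  d <- dim(V)
  clamp01 <- function(g, n) {
    i0 <- pmin(pmax(floor(g), 1), max(n - 1, 1))
    list(i0 = as.integer(i0), f = g - i0)
  }
  cx <- clamp01(gx, d[1]); cy <- clamp01(gy, d[2]); cz <- clamp01(gz, d[3])
  d_out <- c(length(gx), length(gy), length(gz))
  out <- array(0, d_out)
  nxny <- d[1] * d[2]
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ix <- pmin(cx$i0 + a, d[1]); iy <- pmin(cy$i0 + b, d[2]); iz <- pmin(cz$i0 + cc, d[3])
    wx <- if (a == 0) 1 - cx$f else cx$f
    wy <- if (b == 0) 1 - cy$f else cy$f
    wz <- if (cc == 0) 1 - cz$f else cz$f
    w <- outer(outer(wx, wy), wz)
    if (all(w == 0)) next
    lin <- outer(outer(ix, (iy - 1L) * d[1], "+"), (iz - 1L) * nxny, "+")
    out <- out + array(V[lin], d_out) * w
  }
  out
}

#' Fixed-bin-width gray-level discretization
#'
#' Maps HU (or wavelet-band) values inside the mask to integer gray levels
#' `floor((x - anchor) / bin_width) + 1`, clamped below at level 1. Voxels
#' outside the mask get level 0. `Ng` is the highest level present.
#'
#' @param vol A [ct_volume()] (or any object with a `values` array).
#' @param mask Logical array congruent with the volume; must be nonempty.
#' @param bin_width_hu Positive bin width (10 or 35 HU in the default
#'   pipeline).
#' @param anchor_hu Left edge of the first bin. Default −950, the lower edge
#'   of the lung HU window; use `anchor_hu = NULL` to anchor at the in-mask
#'   minimum (the convention used for wavelet bands, whose scale is not HU).
#' @return A `discretized_volume`: list with `levels` (integer array),
#'   `bin_width_hu`, `anchor_hu`, `Ng`, `mask`.
#' @export
discretize <- function(vol, mask, bin_width_hu, anchor_hu = -950) {
  vals <- if (inherits(vol, "ct_volume")) vol$values else vol
  stopifnot(is.array(vals), bin_width_hu > 0)
  if (!identical(dim(mask), dim(vals)) || !any(mask))
    stop("mask must be congruent with the volume and nonempty")
  if (is.null(anchor_hu)) anchor_hu <- min(vals[mask])
  lev <- array(0L, dim(vals))
  lev[mask] <- pmax(1L, as.integer(floor((vals[mask] - anchor_hu) / bin_width_hu)) + 1L)
  structure(
    list(levels = lev, bin_width_hu = bin_width_hu, anchor_hu = anchor_hu,
         Ng = max(lev), mask = mask),
    class = "discretized_volume"
  )
}
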