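# Coiflet-1 analysis filters (standard 6-tap orthonormal pair).
coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(lo = lo, hi = hi)
}

# Apply a 1D FIR filter along one axis of a 3D array.
# y[n] = sum_k h[k] x[n + k - center]; out-of-range indices are wrapped
# ("periodic"), mirrored ("reflect") or zero ("zero").
filter_axis <- function(x, h, axis, center = (length(h) + 1L) %/% 2L,
                        boundary = c("periodic", "reflect", "zero")) {
  boundary <- match.arg(boundary)
  d <- dim(x)
  n <- d[axis]
  out <- array(0, d)
  for (k in seq_along(h)) {
    if (h[k] == 0) next
    src <- seq_len(n) + k - center
    if (boundary == "periodic") {
      src <- ((src - 1L) %% n) + 1L
    } else if (boundary == "reflect") {
      # whole-sample reflection: ... 3 2 1 2 3 ... n-1 n n-1 ...
      p <- 2L * (n - 1L)
      if (p == 0L) { src <- rep(1L, n) } else {
        src <- ((src - 1L) %% p)
        src <- ifelse(src >= n, p - src, src) + 1L
      }
    } else {
      keep <- src >= 1L & src <= n
      dst <- seq_len(n)[keep]
      srck <- src[keep]
      if (length(dst)) {
        out <- out + h[k] * switch(axis,
          { tmp <- array(0, d); tmp[dst, , ] <- x[srck, , , drop = FALSE]; tmp },
          { tmp <- array(0, d); tmp[, dst, ] <- x[, srck, , drop = FALSE]; tmp },
          { tmp <- array(0, d); tmp[, , dst] <- x[, , srck, drop = FALSE]; tmp })
      }
      next
    }
    out <- out + h[k] * switch(axis,
                               x[src, , , drop = FALSE],
                               x[, src, , drop = FALSE],
                               x[, , src, drop = FALSE])
  }
  out
}

#' One-level 3D stationary coiflet wavelet decomposition
#'
#' Undecimated (stationary) separable wavelet transform with the coiflet-1
#' filter pair: each axis is filtered with the low-pass (L) and high-pass
#' (H) analysis filters, giving eight sub-band volumes named by the axis
#' filter order (x, y, z): `LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`, `HHL`,
#' `HHH`. No subsampling is performed, so every band is congruent with the
#' input grid and the lung mask applies unchanged.
#'
#' With periodic boundary handling (the default) the two-channel bank is an
#' exact tight frame: the summed energy of the eight bands equals 8 times
#' the input energy. Reflection padding is available for non-periodic
#' boundaries and also covers axes shorter than the filter.
#'
#' @param vol A [ct_volume()] or 3D numeric array.
#' @param boundary `"periodic"` (default) or `"reflect"`.
#' @return Named list of eight 3D arrays.
#' @export
wavelet_decompose <- function(vol, boundary = c("periodic", "reflect")) {
  boundary <- match.arg(boundary)
  x <- if (inherits(vol, "ct_volume")) vol$values else vol
  stopifnot(length(dim(x)) == 3L)
  f <- coif1_filters()
  bands <- stats::setNames(list(x), "")
  for (ax in 1:3) {
    nxt <- list()
    for (bi in seq_along(bands)) {
      nm <- names(bands)[bi]
      nxt[[paste0(nm, "L")]] <- filter_axis(bands[[bi]], f$lo, ax, boundary = boundary)
      nxt[[paste0(nm, "H")]] <- filter_axis(bands[[bi]], f$hi, ax, boundary = boundary)
    }
    bands <- nxt
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
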