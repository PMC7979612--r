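#' First-order intensity features
#'
#' The 19 first-order statistics of the default registry, computed on the
#' in-mask voxel values: moments (population variance; skewness and
#' kurtosis return 0 on zero variance; kurtosis is the non-excess moment
#' ratio), order statistics, mean absolute deviation, energy and RMS,
#' histogram entropy/uniformity (fixed bin width `hist_bin` anchored at the
#' in-mask minimum), coefficient of variation, quartile coefficient of
#' dispersion, and a box-counting fractal dimension of the above-median
#' binarization (box sizes 1, 2, 4, 8; least-squares slope of
#' `log N(s)` against `log(1/s)`).
#'
#' @param vol A [ct_volume()] or a bare 3D numeric array.
#' @param mask Logical array congruent with the volume.
#' @param hist_bin Histogram bin width for entropy/uniformity (default 35).
#' @param include Optional character vector restricting which features are
#'   computed (all 19 by default).
#' @return Named numeric vector.
#' @export
intensity_features <- function(vol, mask, hist_bin = 35,
                               include = intensity_feature_names()) {
  vals_arr <- if (inherits(vol, "ct_volume")) vol$values else vol
  stopifnot(identical(dim(mask), dim(vals_arr)), any(mask))
  x <- vals_arr[mask]
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  sk <- if (v > 1e-12) sum((x - m)^3) / n / v^1.5 else 0
  ku <- if (v > 1e-12) sum((x - m)^4) / n / v^2 else 0
  hist_p <- {
    lev <- floor((x - min(x)) / hist_bin) + 1
    p <- tabulate(lev) / n
    p[p > 0]
  }
  qcod_den <- q[4] + q[2]
  out <- c(
    mean = m,
    variance = v,
    skewness = sk,
    kurtosis = ku,
    median = q[3],
    minimum = min(x),
    maximum = max(x),
    p10 = q[1],
    p90 = q[5],
    iqr = q[4] - q[2],
    range = max(x) - min(x),
    meanAbsDev = mean(abs(x - m)),
    energy = sum(x^2),
    rms = sqrt(mean(x^2)),
    histEntropy = -sum(hist_p * log2(hist_p)),
    uniformity = sum(hist_p^2),
    cov = if (v > 1e-12 && abs(m) > 1e-12) sqrt(v) / m else 0,
    qcod = if (abs(qcod_den) > 1e-12) (q[4] - q[2]) / qcod_den else 0,
    fractal_dim = NA_real_
  )
  if ("fractal_dim" %in% include)
    out["fractal_dim"] <- fractal_dimension(vals_arr > q[3] & mask)
  out[include]
}

#' @rdname intensity_features
#' @export
intensity_feature_names <- function() {
  c("mean", "variance", "skewness", "kurtosis", "median", "minimum",
    "maximum", "p10", "p90", "iqr", "range", "meanAbsDev", "energy", "rms",
    "histEntropy", "uniformity", "cov", "qcod", "fractal_dim")
}

#' Box-counting fractal dimension of a binary volume
#'
#' Counts occupied boxes at sizes `sizes` over the bounding box of the set
#' and returns the least-squares slope of `log N(s)` versus `log(1/s)`.
#' An empty set returns 0.
#'
#' @param bin 3D logical array.
#' @param sizes Box edge lengths in voxels.
#' @return Estimated dimension (about 3 for a filled solid, 2 for a plane).
#' @export
fractal_dimension <- function(bin, sizes = c(1, 2, 4, 8)) {
  idx <- which(bin)
  if (length(idx) == 0) return(0)
  co <- arrayInd(idx, dim(bin))
  co <- sweep(co, 2, apply(co, 2, min))          # 0-based in bounding box
  counts <- vapply(sizes, function(s) {
    g <- co %/% s
    nrow(unique(g))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[2]
  unname(slope)
}
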