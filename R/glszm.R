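#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level inside the mask.
#' Sixteen zone statistics are computed from the (level, zone size)
#' distribution, including the zone-size variance `sizeVar` (probability-
#' weighted variance of zone sizes) and its normalized variant `sizeVar_n`
#' (`sizeVar` divided by the squared mean zone size — a squared coefficient
#' of variation). Zone entropy is not part of this 16-feature set.
#'
#' @param d A `discretized_volume` from [discretize()].
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(d) {
  zones <- glszm_zone_table(d$levels, d$Ng)
  i <- zones[, 1]; s <- zones[, 2]
  Nz <- nrow(zones)
  Np <- sum(d$levels > 0L)
  if (Nz == 0)
    return(stats::setNames(rep(0, 16), glszm_feature_names()))
  zi <- tabulate(i, nbins = d$Ng)   # zones per gray level
  zs <- tabulate(s)                  # zones per size
  mu_i <- sum(i) / Nz
  mu_s <- sum(s) / Nz
  size_var <- sum((s - mu_s)^2) / Nz
  stats::setNames(c(
    sum(1 / s^2) / Nz,
    sum(s^2) / Nz,
    sum(zi^2) / Nz,
    sum(zi^2) / Nz^2,
    sum(zs^2) / Nz,
    sum(zs^2) / Nz^2,
    Nz / Np,
    sum((i - mu_i)^2) / Nz,
    size_var,
    size_var / mu_s^2,
    sum(1 / i^2) / Nz,
    sum(i^2) / Nz,
    sum(1 / (i^2 * s^2)) / Nz,
    sum(i^2 / s^2) / Nz,
    sum(s^2 / i^2) / Nz,
    sum(i^2 * s^2) / Nz
  ), glszm_feature_names())
}

glszm_feature_names <- function() {
  c("smallZoneEmph", "largeZoneEmph", "grayLevelNonUnifZ",
    "grayLevelNonUnifZ_n", "sizeZoneNonUnif", "sizeZoneNonUnif_n",
    "zonePercentage", "grayLevelVarZ", "sizeVar", "sizeVar_n",
    "lowGrayZoneEmph", "highGrayZoneEmph", "smallZoneLowGrayEmph",
    "smallZoneHighGrayEmph", "largeZoneLowGrayEmph", "largeZoneHighGrayEmph")
}

# (level, size) rows for all zones; per-level labeling on a cropped
# bounding box keeps the flood fill cheap
glszm_zone_table <- function(lev, Ng) {
  out <- vector("list", Ng)
  d <- dim(lev)
  for (g in seq_len(Ng)) {
    idx <- which(lev == g)
    if (length(idx) == 0) next
    co <- arrayInd(idx, d)
    lo <- pmax(1L, apply(co, 2, min) - 1L)
    hi <- pmin(d, apply(co, 2, max) + 1L)
    sub <- lev[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == g
    lab <- label_components_26(sub)
    sizes <- tabulate(lab[lab > 0L])
    out[[g]] <- cbind(level = g, size = sizes)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), 0, 2) else res
}
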