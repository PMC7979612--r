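#' Neighborhood gray-tone difference features
#'
#' Amadasun-King statistics on 26-neighborhoods restricted to the mask:
#' for every in-mask voxel with at least one in-mask neighbor, the absolute
#' difference between its level and the mean level of its neighbors is
#' accumulated per gray level (`s_i`), alongside level occupancy `p_i`.
#'
#' Degenerate conventions: a mask with no neighbor-bearing voxel (single
#' voxel) returns all five features as 0; a constant region has `s = 0`
#' everywhere, so coarseness is capped at `1/eps` with `eps = 1e-12`.
#'
#' @param d A `discretized_volume` from [discretize()].
#' @return Named numeric vector: `coarseness`, `neighContrast`, `busyness`,
#'   `complexity`, `strength`.
#' @export
ngtdm_features <- function(d) {
  st <- ngtdm_table(d$levels, d$Ng)
  if (st$N == 0)
    return(c(coarseness = 0, neighContrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  p <- st$n / st$N
  s <- st$s
  lv <- seq_len(d$Ng)
  present <- p > 0
  Ngp <- sum(present)
  ip <- lv[present]; pp <- p[present]; sp <- s[present]

  eps <- 1e-12
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > eps) 1 / coars_den else 1 / eps

  contrast <- if (Ngp > 1) {
    (sum(outer(pp, pp) * outer(ip, ip, "-")^2) / (Ngp * (Ngp - 1))) *
      (sum(s) / st$N)
  } else 0

  # denominator over all ordered pairs of present levels
  busy_den <- sum(abs(outer(ip * pp, ip * pp, "-")))
  busyness <- if (busy_den > eps) sum(p * s) / busy_den else 0

  complexity <- if (Ngp > 0) {
    num <- outer(ip, ip, function(a, b) abs(a - b)) *
      (outer(pp * sp, pp * sp, "+")) / outer(pp, pp, "+")
    sum(num) / st$N
  } else 0

  strength_den <- sum(s)
  strength <- if (strength_den > eps)
    sum(outer(pp, pp, "+") * outer(ip, ip, "-")^2) / strength_den else 0

  c(coarseness = coarseness, neighContrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

# per-level occupancy n_i and accumulated neighborhood differences s_i
ngtdm_table <- function(lev, Ng) {
  d <- dim(lev)
  inmask <- lev > 0L
  vals <- array(as.numeric(lev), d)
  vals[!inmask] <- 0
  cnt <- array(0, d); tot <- array(0, d)
  offs <- offsets_26()
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    lo <- pmax(1, 1 - off); hi <- pmin(d, d - off)
    if (any(lo > hi)) next
    rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
    sx <- rx + off[1]; sy <- ry + off[2]; sz <- rz + off[3]
    # c() flattens both sides column-major, so thin ranges stay conformable
    tot[rx, ry, rz] <- tot[rx, ry, rz] + c(vals[sx, sy, sz, drop = FALSE])
    cnt[rx, ry, rz] <- cnt[rx, ry, rz] + c(inmask[sx, sy, sz, drop = FALSE])
  }
  use <- inmask & cnt > 0
  if (!any(use)) return(list(n = rep(0, Ng), s = rep(0, Ng), N = 0))
  lv_use <- lev[use]
  diffs <- abs(as.numeric(lv_use) - tot[use] / cnt[use])
  n_i <- tabulate(lv_use, nbins = Ng)
  s_i <- rep(0, Ng)
  agg <- rowsum(diffs, group = lv_use)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  list(n = n_i, s = s_i, N = sum(n_i))
}
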