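#' Gray-level co-occurrence matrices
#'
#' Counts co-occurrences of gray levels at Chebyshev distance 1 along the
#' 13 unique 3D directions, symmetrically (each ordered pair counted both
#' ways). `aggregation = "averaged"` returns the 13 per-direction
#' probability matrices (features are averaged over directions later);
#' `"merged"` sums the counts over directions and normalizes once.
#'
#' @param d A `discretized_volume` from [discretize()].
#' @param aggregation `"averaged"` or `"merged"`.
#' @return For `"merged"` a single Ng x Ng probability matrix; for
#'   `"averaged"` a list of 13 probability matrices (one per direction,
#'   directions as attribute).
#' @export
build_glcm <- function(d, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  counts <- glcm_count_matrices(d$levels, d$Ng)
  if (aggregation == "merged") {
    m <- Reduce(`+`, counts)
    s <- sum(m)
    if (s == 0) stop("no voxel pairs inside the mask")
    return(m / s)
  }
  lapply(counts, function(m) {
    s <- sum(m)
    if (s > 0) m / s else m
  })
}

# 13 symmetric count matrices, one per unique direction
glcm_count_matrices <- function(lev, Ng) {
  d <- dim(lev)
  offs <- offsets_13()
  lapply(seq_len(nrow(offs)), function(k) {
    off <- offs[k, ]
    lo <- pmax(1, 1 - off); hi <- pmin(d, d - off)
    if (any(lo > hi)) return(matrix(0, Ng, Ng))
    rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
    A <- lev[rx, ry, rz, drop = FALSE]
    B <- lev[rx + off[1], ry + off[2], rz + off[3], drop = FALSE]
    ok <- A > 0L & B > 0L
    m <- matrix(0, Ng, Ng)
    if (any(ok)) {
      tab <- tabulate((A[ok] - 1L) * Ng + B[ok], nbins = Ng * Ng)
      m <- matrix(tab, Ng, Ng, byrow = TRUE)
      m <- m + t(m)   # symmetric: count both orders
    }
    m
  })
}

#' Co-occurrence matrix features
#'
#' The 26 co-occurrence statistics of the default registry evaluated on one
#' probability-normalized GLCM. `homogenity`/`homogenity_n` are the inverse
#' difference and its gray-level-normalized variant (the registry keeps the
#' study's spelling); `jointEnergy` is the angular second moment
#' `sum(p^2)`. Correlation returns 0 when the marginal variance vanishes;
#' the maximal correlation coefficient returns 1 for a single-level matrix.
#'
#' @param P Square nonnegative matrix summing to 1.
#' @return Named numeric vector of length 26.
#' @export
glcm_features <- function(P) {
  Ng <- nrow(P)
  stopifnot(ncol(P) == Ng, abs(sum(P) - 1) < 1e-8)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(Ng) * px); mu_y <- sum(seq_len(Ng) * py)
  var_x <- sum((seq_len(Ng) - mu_x)^2 * px)
  var_y <- sum((seq_len(Ng) - mu_y)^2 * py)

  # diagonal (i+j) and cross (|i-j|) marginals
  psum <- sapply(2:(2 * Ng), function(k) sum(P[i + j == k]))
  ks <- 2:(2 * Ng)
  pdiff <- sapply(0:(Ng - 1), function(k) sum(P[abs(i - j) == k]))
  kd <- 0:(Ng - 1)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  sum_avg <- sum(ks * psum)
  diff_avg <- sum(kd * pdiff)
  joint_avg <- sum(i * P)

  hxy <- ent(P)
  pxy_prod <- outer(px, py)
  nz <- P > 0 & pxy_prod > 0
  hxy1 <- -sum(P[nz] * log2(pxy_prod[nz]))
  nzm <- pxy_prod > 0
  hxy2 <- -sum(pxy_prod[nzm] * log2(pxy_prod[nzm]))
  hx <- ent(px); hy <- ent(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  corr <- if (var_x > 1e-12 && var_y > 1e-12)
    (sum(i * j * P) - mu_x * mu_y) / sqrt(var_x * var_y) else 0

  mcc <- glcm_mcc(P, px, py)

  dsq <- (i - j)^2
  c(
    jointMax = max(P),
    jointAverage = joint_avg,
    jointVariance = sum((i - joint_avg)^2 * P),
    jointEntropy = hxy,
    sumAverage = sum_avg,
    sumVariance = sum((ks - sum_avg)^2 * psum),
    sumEntropy = ent(psum),
    diffAverage = diff_avg,
    diffVariance = sum((kd - diff_avg)^2 * pdiff),
    diffEntropy = ent(pdiff),
    jointEnergy = sum(P^2),
    contrast = sum(dsq * P),
    dissimilarity = sum(abs(i - j) * P),
    homogenity = sum(P / (1 + abs(i - j))),
    homogenity_n = sum(P / (1 + abs(i - j) / Ng)),
    idm = sum(P / (1 + dsq)),
    idm_n = sum(P / (1 + dsq / Ng^2)),
    inverseVariance = sum(P[i != j] / dsq[i != j]),
    correlation = corr,
    autocorrelation = sum(i * j * P),
    clusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    clusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    clusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    imc1 = imc1,
    imc2 = imc2,
    mcc = mcc
  )
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q[i,j] = sum_k P[i,k] P[j,k] / (px[i] py[k]), on present levels only
glcm_mcc <- function(P, px = rowSums(P), py = colSums(P)) {
  keep <- px > 0
  if (sum(keep) < 2 || sum(py > 0) < 2) return(1)
  Pk <- P[keep, py > 0, drop = FALSE]
  pxk <- px[keep]; pyk <- py[py > 0]
  Q <- (Pk / pxk) %*% t(Pk / rep(pyk, each = nrow(Pk)))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(ev[2], 1)))
}

# 26 averaged + 26 merged ("M_" prefixed) GLCM features of one volume
glcm_feature_set <- function(d) {
  counts <- glcm_count_matrices(d$levels, d$Ng)
  per_dir <- lapply(counts, function(m) {
    s <- sum(m)
    if (s == 0) return(NULL)
    glcm_features(m / s)
  })
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  avg <- Reduce(`+`, per_dir) / length(per_dir)
  merged_m <- Reduce(`+`, counts)
  merged <- glcm_features(merged_m / sum(merged_m))
  names(merged) <- paste0("M_", names(merged))
  c(avg, merged)
}
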