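#' Gray-level run-length features
#'
#' Run-length matrices are built along the 13 unique 3D directions; runs are
#' maximal sequences of collinear in-mask voxels sharing one gray level
#' (mask gaps break runs). Sixteen conventional statistics are computed per
#' direction and averaged (`aggregation = "averaged"`), or computed once on
#' the direction-summed matrix (`"merged"`; run percentage then uses
#' `13 * Np` as its denominator since every voxel is scanned 13 times).
#'
#' @param d A `discretized_volume` from [discretize()].
#' @param aggregation `"averaged"` or `"merged"`.
#' @return Named numeric vector of 16 features (prefixed `M_` when merged).
#' @export
glrlm_features <- function(d, aggregation = c("averaged", "merged")) {
  aggregation <- match.arg(aggregation)
  Np <- sum(d$levels > 0L)
  runs <- glrlm_run_tables(d$levels, d$Ng)
  if (aggregation == "averaged") {
    per <- lapply(runs, glrlm_stats_from_runs, Ng = d$Ng, Np = Np)
    out <- Reduce(`+`, per) / length(per)
  } else {
    all_runs <- do.call(rbind, runs)
    out <- glrlm_stats_from_runs(all_runs, Ng = d$Ng, Np = 13 * Np)
    names(out) <- paste0("M_", names(out))
  }
  out
}

# per direction: matrix with columns (level, length) - one row per run
glrlm_run_tables <- function(lev, Ng) {
  d <- dim(lev)
  idx <- which(lev > 0L)
  co <- arrayInd(idx, d)
  lv <- lev[idx]
  offs <- offsets_13()
  lapply(seq_len(nrow(offs)), function(k) {
    off <- offs[k, ]
    step <- sum(off^2)
    s <- co[, 1] * off[1] + co[, 2] * off[2] + co[, 3] * off[3]
    # cross-product components are invariant along a line of direction off
    u <- co[, 1] * off[2] - co[, 2] * off[1]
    v <- co[, 1] * off[3] - co[, 3] * off[1]
    w <- co[, 2] * off[3] - co[, 3] * off[2]
    o <- order(u, v, w, s)
    if (length(o) == 0) return(matrix(numeric(0), 0, 2))
    same_line <- diff(u[o]) == 0 & diff(v[o]) == 0 & diff(w[o]) == 0
    contiguous <- diff(s[o]) == step
    same_level <- diff(lv[o]) == 0
    new_run <- c(TRUE, !(same_line & contiguous & same_level))
    run_id <- cumsum(new_run)
    cbind(level = lv[o][new_run], length = tabulate(run_id))
  })
}

glrlm_stats_from_runs <- function(runs, Ng, Np) {
  if (nrow(runs) == 0)
    return(stats::setNames(rep(0, 16), glrlm_feature_names()))
  i <- runs[, 1]; l <- runs[, 2]
  Nr <- nrow(runs)
  p <- rep(1 / Nr, Nr)
  ri <- tabulate(i, nbins = Ng)                 # runs per gray level
  rl <- tabulate(l)                              # runs per length
  mu_i <- sum(i) / Nr; mu_l <- sum(l) / Nr
  ent_p <- local({
    # entropy over distinct (level, length) cells
    key <- paste(i, l)
    cnt <- table(key) / Nr
    -sum(cnt * log2(cnt))
  })
  stats::setNames(c(
    sum(1 / l^2) / Nr,
    sum(l^2) / Nr,
    sum(ri^2) / Nr,
    sum(ri^2) / Nr^2,
    sum(rl^2) / Nr,
    sum(rl^2) / Nr^2,
    Nr / Np,
    sum(1 / i^2) / Nr,
    sum(i^2) / Nr,
    sum(1 / (i^2 * l^2)) / Nr,
    sum(i^2 / l^2) / Nr,
    sum(l^2 / i^2) / Nr,
    sum(i^2 * l^2) / Nr,
    sum((i - mu_i)^2) / Nr,
    sum((l - mu_l)^2) / Nr,
    ent_p
  ), glrlm_feature_names())
}

glrlm_feature_names <- function() {
  c("shortRunEmph", "longRunEmph", "grayLevelNonUnif", "grayLevelNonUnif_n",
    "runLengthNonUnif", "runLengthNonUnif_n", "runPercentage",
    "lowGrayRunEmph", "highGrayRunEmph", "shortRunLowGrayEmph",
    "shortRunHighGrayEmph", "longRunLowGrayEmph", "longRunHighGrayEmph",
    "grayLevelVar", "runLengthVar", "runEntropy")
}
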