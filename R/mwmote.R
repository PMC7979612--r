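#' MWMOTE configuration
#'
#' Hyper-parameters of the majority-weighted minority oversampling
#' technique. Defaults follow the algorithm's original publication, except
#' `k3`, which defaults to half the minority count (rounded up, at least 1)
#' to stay meaningful for very small minorities.
#'
#' @param k1 Neighborhood size for filtering noisy minority points.
#' @param k2 Majority neighbors defining the borderline majority set.
#' @param k3 Minority neighbors of borderline majority points
#'   (`"half-minority"` or an integer).
#' @param cf_th Closeness-factor cutoff.
#' @param cmax Closeness-factor scale.
#' @param cp Cluster-distance multiplier for average-linkage clustering of
#'   the minority class.
#' @param target `"balance-to-majority"` or an explicit total minority
#'   count after augmentation.
#' @param seed Integer seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(k1 = 5, k2 = 3, k3 = "half-minority",
                                cf_th = 5, cmax = 2, cp = 3,
                                target = "balance-to-majority", seed = 1L) {
  stopifnot(k1 >= 1, k2 >= 1, cf_th > 0, cmax > 0, cp > 0)
  if (!identical(k3, "half-minority")) stopifnot(k3 >= 1)
  structure(list(k1 = k1, k2 = k2, k3 = k3, cf_th = cf_th, cmax = cmax,
                 cp = cp, target = target, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Majority-weighted minority oversampling (MWMOTE)
#'
#' Balances a binary-labeled feature table by generating synthetic minority
#' samples: (1) minority points with no minority among their `k1` nearest
#' neighbors are filtered out as noise; (2) the `k2` nearest majority
#' neighbors of the remaining minority points form the borderline majority
#' set; (3) the `k3` nearest minority neighbors of those majority points
#' form the informative minority set; (4) each informative minority point
#' receives a selection weight summing closeness x density factors over the
#' borderline majority; (5) the minority class is clustered by
#' average-linkage agglomeration cut at `cp` times the mean nearest-
#' minority-neighbor distance; (6) synthetics are `x + alpha (z - x)` with
#' `alpha ~ U(0,1)`, `x` drawn by selection weight and `z` uniformly from
#' `x`'s cluster. All original rows are preserved; exactly
#' `target - minority count` synthetics are appended.
#'
#' A minority of size 1 falls back to plain duplication with a warning
#' (the algorithm's neighborhoods are undefined). Distance ties are broken
#' by index order.
#'
#' @param X Numeric matrix or data frame of features (rows = samples).
#' @param y Binary label vector (factor, character or numeric).
#' @param cfg An [augmentation_config()].
#' @return List: `X_aug`, `y_aug` (originals first, synthetics appended),
#'   `provenance` (data frame with minority row indices `x`, `z` and
#'   `alpha` per synthetic) and `weights` (named selection probabilities
#'   over minority rows).
#' @export
mwmote_oversample <- function(X, y, cfg = augmentation_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(X) == length(y))
  tab <- table(y)
  if (tab[1] == tab[2]) stop("classes already balanced; minority must be strictly smaller")
  minority_level <- names(tab)[which.min(tab)]
  min_idx <- which(y == minority_level)
  maj_idx <- which(y != minority_level)
  n_min <- length(min_idx)
  target_n <- if (identical(cfg$target, "balance-to-majority"))
    length(maj_idx) else as.integer(cfg$target)
  n_syn <- target_n - n_min
  if (n_syn <= 0) stop("target does not exceed the minority count")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  if (n_min == 1L) {
    warning("minority of size 1: MWMOTE undefined, duplicating the single minority sample")
    Xs <- X[rep(min_idx, n_syn), , drop = FALSE]
    prov <- data.frame(x = rep(min_idx, n_syn), z = rep(min_idx, n_syn),
                       alpha = rep(0, n_syn))
    return(build_augmented(X, y, Xs, minority_level, prov,
                           stats::setNames(1, rownames(X)[min_idx])))
  }

  k3 <- if (identical(cfg$k3, "half-minority")) max(1L, ceiling(n_min / 2)) else
    min(cfg$k3, n_min)

  D <- as.matrix(stats::dist(X))
  # ties broken by index order: order(distance, index)
  knn_of <- function(i, candidates, k) {
    cand <- setdiff(candidates, i)
    cand[order(D[i, cand], cand)][seq_len(min(k, length(cand)))]
  }

  # stage 1: filtered minority
  filtered <- min_idx[vapply(min_idx, function(i) {
    nb <- knn_of(i, seq_len(nrow(X)), cfg$k1)
    any(nb %in% min_idx)
  }, logical(1))]
  if (length(filtered) == 0) filtered <- min_idx

  # stage 2: borderline majority
  border_maj <- sort(unique(unlist(lapply(filtered, knn_of,
                                          candidates = maj_idx, k = cfg$k2))))
  # stage 3: informative minority
  informative <- sort(unique(unlist(lapply(border_maj, knn_of,
                                           candidates = min_idx, k = k3))))

  # stage 4: information weights
  p <- ncol(X)
  closeness <- function(yv, xv) {
    dxy <- D[yv, xv]
    cf <- if (dxy < 1e-12) cfg$cf_th else min(cfg$cf_th, p / dxy)
    cf / cfg$cf_th * cfg$cmax
  }
  W <- matrix(0, length(border_maj), length(informative))
  for (a in seq_along(border_maj)) {
    cfv <- vapply(informative, function(xv) closeness(border_maj[a], xv), numeric(1))
    W[a, ] <- cfv * (cfv / sum(cfv))         # closeness x density factor
  }
  sel_w <- colSums(W)
  sel_p <- sel_w / sum(sel_w)

  # stage 5: average-linkage clustering of the whole minority class
  Dmin <- D[min_idx, min_idx]
  nn_dist <- vapply(seq_len(n_min), function(i) min(Dmin[i, -i]), numeric(1))
  cut_h <- cfg$cp * mean(nn_dist)
  cl <- stats::cutree(stats::hclust(stats::as.dist(Dmin), method = "average"),
                      h = cut_h)

  # stage 6: synthetic generation
  pick_x <- informative[sample.int(length(informative), n_syn,
                                   replace = TRUE, prob = sel_p)]
  alpha <- stats::runif(n_syn)
  pick_z <- vapply(pick_x, function(xi) {
    members <- min_idx[cl == cl[match(xi, min_idx)]]
    if (length(members) == 1L) members else
      members[sample.int(length(members), 1L)]
  }, numeric(1))
  Xs <- X[pick_x, , drop = FALSE] +
    alpha * (X[pick_z, , drop = FALSE] - X[pick_x, , drop = FALSE])
  prov <- data.frame(x = pick_x, z = pick_z, alpha = alpha)
  weights <- stats::setNames(rep(0, n_min), min_idx)
  weights[as.character(informative)] <- sel_p
  build_augmented(X, y, Xs, minority_level, prov, weights)
}

build_augmented <- function(X, y, Xs, minority_level, prov, weights) {
  rownames(Xs) <- sprintf("syn%03d", seq_len(nrow(Xs)))
  X_aug <- rbind(X, Xs)
  y_aug <- factor(c(as.character(y), rep(minority_level, nrow(Xs))),
                  levels = levels(y))
  list(X_aug = X_aug, y_aug = y_aug, provenance = prov, weights = weights)
}

#' Class imbalance ratio
#'
#' Minority over majority count, rounded to two decimals (a 54/6 cohort has
#' ratio 0.11).
#'
#' @param y Binary label vector.
#' @return Numeric scalar.
#' @export
imbalance_ratio <- function(y) {
  tab <- table(factor(y))
  stopifnot(length(tab) == 2L)
  round(min(tab) / max(tab), 2)
}
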