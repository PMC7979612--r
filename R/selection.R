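#' Selection pipeline configuration
#'
#' @param split_ratio Training fraction for [stratified_split()] (default
#'   0.7).
#' @param r_threshold Pearson correlation defining a cluster of collinear
#'   features (default 0.60).
#' @param boruta_max_runs,boruta_alpha Shadow-feature loop length and test
#'   level for [boruta_select()].
#' @param n_trees Random-forest size used by Boruta and cluster
#'   representatives.
#' @param bootstrap_reps ROC bootstrap replicates (default 2000).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return A `selection_config` list.
#' @export
selection_config <- function(split_ratio = 0.7, r_threshold = 0.60,
                             boruta_max_runs = 100, boruta_alpha = 0.05,
                             n_trees = 500, bootstrap_reps = 2000,
                             cv_folds = 10, seed = 1L) {
  stopifnot(split_ratio > 0, split_ratio < 1, r_threshold > 0, r_threshold <= 1,
            boruta_max_runs >= 5, boruta_alpha > 0, boruta_alpha < 1,
            n_trees >= 10, bootstrap_reps >= 10, cv_folds >= 2)
  structure(as.list(environment()), class = "selection_config")
}

#' Z-score standardization fitted on the training split
#'
#' Column means and standard deviations are estimated on the training table
#' only and applied to every supplied table, preventing test-set leakage.
#' Zero-variance training columns are dropped from all outputs with a
#' warning.
#'
#' @param train Numeric matrix / data frame (training split).
#' @param ... Further tables to transform with the training moments.
#' @return List: `train`, one transformed element per extra table (named as
#'   passed), `center`, `scale`, `dropped`.
#' @export
zscore_standardize <- function(train, ...) {
  train <- as.matrix(train)
  extras <- lapply(list(...), as.matrix)
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  drop <- sdv < 1e-12
  if (any(drop))
    warning("dropping zero-variance feature(s): ",
            paste(utils::head(colnames(train)[drop], 5), collapse = ", "))
  keep <- !drop
  tf <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2,
                          sdv[keep], "/")
  out <- c(list(train = tf(train)), lapply(extras, tf))
  out$center <- mu[keep]; out$scale <- sdv[keep]
  out$dropped <- colnames(train)[drop]
  out
}

#' Stratified train/test split
#'
#' Per class, `round(ratio * n)` shuffled samples go to the training split,
#' the remainder to the test split (54 + 54 at ratio 0.7 gives 38 + 38
#' train and 16 + 16 test).
#'
#' @param n Number of samples (or a data frame/matrix whose rows are
#'   split).
#' @param labels Class labels, length `n`.
#' @param ratio Training fraction.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(n, labels, ratio = 0.7, seed = 1L) {
  if (!is.numeric(n) || length(n) > 1) n <- nrow(n)
  labels <- factor(labels)
  stopifnot(length(labels) == n, ratio > 0, ratio < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    k <- round(ratio * length(idx))
    train <- c(train, sample(idx)[seq_len(k)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Boruta all-relevant feature selection
#'
#' Repeatedly appends a permuted "shadow" copy of every feature, fits a
#' random forest (impurity importance), and records a hit whenever a real
#' feature out-scores the best shadow. Features are confirmed or rejected
#' by sequential two-sided binomial tests of the hit count against chance
#' (p = 0.5) at `alpha` with Bonferroni correction over the features still
#' undecided; the loop stops early once nothing is undecided. Features
#' still tentative after `max_runs` are resolved by comparing their median
#' importance with the median of the best-shadow importances.
#'
#' @param X Numeric matrix / data frame of features (training split).
#' @param y Binary labels.
#' @param cfg A [selection_config()].
#' @return List: `decision` (named factor: confirmed / rejected),
#'   `confirmed` (names), `hits`, `runs`, `tentative_resolved` (names
#'   resolved by the median heuristic).
#' @export
boruta_select <- function(X, y, cfg = selection_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  if (min(table(y)) < 5) stop("need at least 5 samples per class")
  p <- ncol(X); n <- nrow(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- colnames(X) <- paste0("V", seq_len(p))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  hits <- stats::setNames(rep(0L, p), feat)
  status <- stats::setNames(rep("undecided", p), feat)
  imp_hist <- matrix(NA_real_, cfg$boruta_max_runs, p,
                     dimnames = list(NULL, feat))
  shadow_max_hist <- rep(NA_real_, cfg$boruta_max_runs)
  runs <- 0L
  for (r in seq_len(cfg$boruta_max_runs)) {
    runs <- r
    shadows <- apply(X, 2, sample)
    colnames(shadows) <- paste0("shadow_", feat)
    df <- data.frame(.y = y, X, shadows, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = cfg$n_trees, importance = "impurity",
      seed = cfg$seed + r, num.threads = 1
    )
    imp <- fit$variable.importance
    sh_max <- max(imp[paste0("shadow_", feat)])
    shadow_max_hist[r] <- sh_max
    real <- imp[feat]
    imp_hist[r, ] <- real
    hits <- hits + as.integer(real > sh_max)

    und <- names(status)[status == "undecided"]
    if (r >= 5L && length(und)) {
      alpha_adj <- cfg$boruta_alpha / length(und)
      p_hi <- stats::pbinom(hits[und] - 1L, r, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[und], r, 0.5)
      status[und][2 * p_hi < alpha_adj] <- "confirmed"
      status[und][2 * p_lo < alpha_adj] <- "rejected"
    }
    if (!any(status == "undecided")) break
  }
  tentative <- names(status)[status == "undecided"]
  if (length(tentative)) {
    med_sh <- stats::median(shadow_max_hist[seq_len(runs)])
    med_imp <- apply(imp_hist[seq_len(runs), tentative, drop = FALSE], 2,
                     stats::median)
    status[tentative] <- ifelse(med_imp > med_sh, "confirmed", "rejected")
  }
  list(decision = factor(status, levels = c("confirmed", "rejected")),
       confirmed = names(status)[status == "confirmed"],
       hits = hits, runs = runs, tentative_resolved = tentative)
}

#' Correlation clustering of selected features
#'
#' Hierarchical agglomerative clustering with distance `1 - |Pearson r|`
#' and average linkage; the dendrogram is cut at `1 - r_threshold`, so
#' features whose absolute pairwise correlation reaches the threshold end
#' up together. Singleton clusters are allowed.
#'
#' @param X Numeric matrix / data frame (features in columns).
#' @param r_threshold Correlation threshold (default 0.60).
#' @return Named integer vector mapping feature name to cluster id.
#' @export
correlation_clusters <- function(X, r_threshold = 0.60) {
  X <- as.matrix(X)
  if (ncol(X) == 1L) return(stats::setNames(1L, colnames(X)))
  cm <- abs(stats::cor(X))
  cm[!is.finite(cm)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  stats::cutree(hc, h = 1 - r_threshold)
}

#' Gini-importance cluster representative
#'
#' Fits a seeded random forest on the cluster's features only and returns
#' the feature with the largest mean-decrease-in-impurity importance; ties
#' break lexicographically.
#'
#' @param X Numeric matrix / data frame (training split).
#' @param y Binary labels.
#' @param members Feature names forming the cluster.
#' @param n_trees,seed Forest size and seed.
#' @return A single feature name.
#' @export
cluster_representative <- function(X, y, members, n_trees = 500, seed = 1L) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1L) return(members)
  X <- as.matrix(X)[, members, drop = FALSE]
  df <- data.frame(.y = factor(y), X, check.names = FALSE)
  # mtry = all members: every split sees the whole cluster, so impurity
  # importance concentrates on the member that separates the classes best
  # instead of being shared at random among collinear copies
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees, importance = "impurity",
                        mtry = length(members), seed = seed, num.threads = 1)
  imp <- fit$variable.importance[members]
  members[order(-imp, members)][1]
}

#' Boruta + correlation-cluster selection funnel
#'
#' The full dimension-reduction sequence applied to a training table:
#' Boruta confirmation, correlation clustering of the confirmed features at
#' `r_threshold`, and one Gini representative per cluster.
#'
#' @inheritParams boruta_select
#' @return List: `confirmed`, `clusters` (named map on confirmed features),
#'   `representatives` (one feature name per cluster).
#' @export
select_features <- function(X, y, cfg = selection_config()) {
  bor <- boruta_select(X, y, cfg)
  if (length(bor$confirmed) == 0)
    return(list(confirmed = character(0), clusters = integer(0),
                representatives = character(0), boruta = bor))
  cl <- correlation_clusters(as.matrix(X)[, bor$confirmed, drop = FALSE],
                             cfg$r_threshold)
  reps <- vapply(sort(unique(cl)), function(k) {
    cluster_representative(X, y, names(cl)[cl == k],
                           n_trees = cfg$n_trees, seed = cfg$seed + 1000L + k)
  }, character(1))
  list(confirmed = bor$confirmed, clusters = cl, representatives = reps,
       boruta = bor)
}
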