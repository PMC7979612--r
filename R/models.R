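#' Logistic models compared by AIC
#'
#' Fits one maximum-likelihood logistic regression (IRLS via `glm`,
#' tolerance 1e-8, up to 100 iterations) per term set and returns the
#' reports sorted by AIC (`2k - 2 logL`, `k` = terms + intercept).
#' Quasi-complete separation (non-convergence or divergent coefficients)
#' is flagged in the report; the AIC at the capped iteration is still
#' reported. An empty term set fits the intercept-only model.
#'
#' @param X Numeric matrix / data frame of predictors.
#' @param y Binary labels (second factor level modeled as the event).
#' @param term_sets List of character vectors of predictor names.
#' @return Data frame: `terms`, `k`, `aic`, `log_lik`, `converged`,
#'   `separation`; attribute `fits` holds the `glm` objects in the sorted
#'   order.
#' @export
fit_logistic_aic <- function(X, y, term_sets) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L)
  reports <- lapply(term_sets, function(terms) {
    df <- cbind(.y = y, X)
    fml <- if (length(terms) == 0) stats::as.formula(".y ~ 1") else
      stats::reformulate(sprintf("`%s`", terms), response = ".y")
    fit <- suppressWarnings(stats::glm(
      fml, data = df, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    ))
    coefs <- stats::coef(fit)[-1]
    sep <- !fit$converged || any(abs(coefs) > 15, na.rm = TRUE)
    list(report = data.frame(
      terms = paste(terms, collapse = " + "),
      k = length(terms) + 1L,
      aic = stats::AIC(fit),
      log_lik = as.numeric(stats::logLik(fit)),
      converged = fit$converged,
      separation = sep,
      stringsAsFactors = FALSE
    ), fit = fit)
  })
  tab <- do.call(rbind, lapply(reports, `[[`, "report"))
  o <- order(tab$aic)
  out <- tab[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- lapply(reports, `[[`, "fit")[o]
  out
}

#' ROC analysis with bootstrapped confidence interval
#'
#' Trapezoidal AUC over all score thresholds, a stratified nonparametric
#' bootstrap percentile 95% CI, and the Youden-J operating point with its
#' sensitivity and specificity. Higher scores are taken to indicate the
#' positive (second factor level) class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param bootstrap_reps Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List: `auc`, `ci` (length-2), `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
roc_analysis <- function(scores, labels, bootstrap_reps = 2000, seed = 1L) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, length(scores) == length(labels))
  pos <- labels == levels(labels)[2]
  auc <- auc_trapezoid(scores, pos)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ip <- which(pos); inn <- which(!pos)
  boots <- vapply(seq_len(bootstrap_reps), function(b) {
    bi <- c(sample(ip, length(ip), replace = TRUE),
            sample(inn, length(inn), replace = TRUE))
    auc_trapezoid(scores[bi], pos[bi])
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))

  # Youden-J operating point over the observed thresholds
  thr <- sort(unique(scores))
  cand <- c(-Inf, (thr[-1] + thr[-length(thr)]) / 2, Inf)
  stats_at <- vapply(cand, function(t) {
    sens <- mean(scores[pos] > t)
    spec <- mean(scores[!pos] <= t)
    c(sens, spec)
  }, numeric(2))
  j <- stats_at[1, ] + stats_at[2, ] - 1
  best <- which.max(j)
  list(auc = auc, ci = ci,
       sensitivity = stats_at[1, best], specificity = stats_at[2, best],
       threshold = cand[best])
}

# Mann-Whitney formulation of the trapezoidal AUC (ties counted 1/2)
auc_trapezoid <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Refits the logistic model on each training fold and scores the held-out
#' fold at probability threshold 0.5; every sample is scored exactly once.
#' The pooled accuracy gets an exact binomial (Clopper-Pearson) 95% CI.
#'
#' @param X Numeric matrix / data frame of predictors.
#' @param y Binary labels.
#' @param terms Predictor names of the model.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return List: `accuracy`, `ci`, `fold_id`, `predicted`.
#' @export
cross_validate <- function(X, y, terms, folds = 10, seed = 1L) {
  X <- as.data.frame(X, check.names = FALSE)
  y <- factor(y)
  n <- nrow(X)
  stopifnot(nlevels(y) == 2L, length(y) == n, folds >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- integer(n)
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- factor(rep(levels(y)[1], n), levels = levels(y))
  df <- cbind(.y = y, X)
  fml <- if (length(terms) == 0) stats::as.formula(".y ~ 1") else
    stats::reformulate(sprintf("`%s`", terms), response = ".y")
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- suppressWarnings(stats::glm(fml, data = df[!hold, , drop = FALSE],
                                       family = stats::binomial(),
                                       control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    pr <- stats::predict(fit, newdata = df[hold, , drop = FALSE], type = "response")
    pred[hold] <- ifelse(pr > 0.5, levels(y)[2], levels(y)[1])
  }
  acc <- mean(pred == y)
  bt <- stats::binom.test(sum(pred == y), n)
  list(accuracy = acc, ci = unname(bt$conf.int), fold_id = fold_id,
       predicted = pred)
}

#' Evaluate a fitted logistic model on a labeled dataset
#'
#' Convenience wrapper producing the ROC-based performance report for one
#' dataset tag (train / test / original).
#'
#' @param fit A `glm` logistic fit.
#' @param X Data frame of predictors.
#' @param y Binary labels.
#' @param tag Dataset tag string.
#' @param bootstrap_reps,seed Passed to [roc_analysis()].
#' @return One-row data frame: `tag`, `auc`, `auc_lo`, `auc_hi`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_model <- function(fit, X, y, tag = "test", bootstrap_reps = 2000,
                           seed = 1L) {
  sc <- stats::predict(fit, newdata = as.data.frame(X, check.names = FALSE),
                       type = "response")
  r <- roc_analysis(sc, y, bootstrap_reps = bootstrap_reps, seed = seed)
  data.frame(tag = tag, auc = r$auc, auc_lo = r$ci[1], auc_hi = r$ci[2],
             sensitivity = r$sensitivity, specificity = r$specificity,
             stringsAsFactors = FALSE)
}
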