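test_that("the intercept-only model reproduces the closed-form AIC", {
  y <- factor(rep(c("a", "b"), 4))
  tab <- fit_logistic_aic(data.frame(x = rnorm(8)), y, list(character(0)))
  expect_equal(tab$log_lik, 8 * log(0.5), tolerance = 1e-6)
  expect_equal(tab$aic, 2 - 2 * 8 * log(0.5), tolerance = 1e-6)
})

test_that("adding a pure-noise term costs the AIC penalty net of chance fit", {
  # AIC difference = 2 (penalty) - likelihood-ratio statistic; under the
  # null the statistic is approximately chi-squared(1) with mean ~1, so the
  # expected shift is about +1 (slightly below in finite samples)
  diffs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      df <- data.frame(x = rnorm(80), z = rnorm(80))
    })
    y <- factor(rep(c("a", "b"), each = 40))
    tab <- fit_logistic_aic(df, y, list("x", c("x", "z")))
    tab$aic[tab$terms == "x + z"] - tab$aic[tab$terms == "x"]
  }, numeric(1))
  expect_gt(mean(diffs), 0.4)
  expect_lt(mean(diffs), 1.6)
})

test_that("reports come back sorted by AIC with the strongest model first", {
  withr::with_seed(3, {
    df <- data.frame(good = c(rnorm(40), rnorm(40, 3)), junk = rnorm(80))
  })
  y <- factor(rep(c("a", "b"), each = 40))
  tab <- fit_logistic_aic(df, y, list("junk", "good"))
  expect_equal(tab$terms[1], "good")
  expect_true(all(diff(tab$aic) >= 0))
})

test_that("separation is flagged but AIC still reported", {
  df <- data.frame(sep = c(rep(0, 20), rep(1, 20)))
  y <- factor(rep(c("a", "b"), each = 20))
  tab <- fit_logistic_aic(df, y, list("sep"))
  expect_true(tab$separation[1])
  expect_true(is.finite(tab$aic[1]))
})

test_that("perfectly separated scores give AUC, sensitivity and specificity 1", {
  r <- roc_analysis(c(1:5, 11:15), rep(c("a", "b"), each = 5),
                    bootstrap_reps = 100, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2] + 1e-12)
})

test_that("label-independent scores give a null AUC near one half", {
  withr::with_seed(2, {
    sc <- rnorm(200)
  })
  y <- rep(c("a", "b"), each = 100)
  r <- roc_analysis(sc, y, bootstrap_reps = 100, seed = 2)
  expect_lt(abs(r$auc - 0.5), 0.1)
})

test_that("negating the scores flips the AUC around one half", {
  withr::with_seed(4, {
    sc <- rnorm(60)
  })
  y <- rep(c("a", "b"), 30)
  a1 <- roc_analysis(sc, y, bootstrap_reps = 10, seed = 1)$auc
  a2 <- roc_analysis(-sc, y, bootstrap_reps = 10, seed = 1)$auc
  expect_equal(a1, 1 - a2, tolerance = 1e-12)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    sc <- rnorm(80) + rep(c(0, 1.2), each = 40)
  })
  y <- rep(c("a", "b"), each = 40)
  ours <- roc_analysis(sc, y, bootstrap_reps = 10, seed = 1)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, levels = c("a", "b"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("cross-validation scores every sample exactly once and nails a perfect predictor", {
  withr::with_seed(5, {
    df <- data.frame(x = c(rnorm(50), rnorm(50, 8)))
  })
  y <- factor(rep(c("a", "b"), each = 50))
  cv <- cross_validate(df, y, "x", folds = 10, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_equal(as.integer(table(cv$fold_id)), rep(10L, 10))
})

test_that("cross-validated accuracy is near chance for label-independent features", {
  withr::with_seed(7, {
    df <- data.frame(x = rnorm(100))
  })
  y <- factor(rep(c("a", "b"), each = 50))
  cv <- cross_validate(df, y, "x", folds = 10, seed = 4)
  expect_lt(abs(cv$accuracy - 0.5), 0.15)
  expect_true(cv$ci[1] <= cv$accuracy && cv$accuracy <= cv$ci[2])
})
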