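test_that("z-scoring is fitted on the training split only", {
  withr::with_seed(1, {
    train <- matrix(rnorm(200, 5, 2), 50, 4,
                    dimnames = list(NULL, paste0("f", 1:4)))
    test <- matrix(rnorm(80, 9, 2), 20, 4,
                   dimnames = list(NULL, paste0("f", 1:4)))
  })
  zs <- zscore_standardize(train, test = test)
  expect_lt(max(abs(colMeans(zs$train))), 1e-9)
  expect_lt(max(abs(apply(zs$train, 2, sd) - 1)), 1e-9)
  # test columns standardized with *train* moments keep their shift
  expect_gt(min(colMeans(zs$test)), 1)
})

test_that("constant columns are dropped with a warning", {
  train <- cbind(a = rnorm(30), b = rep(2, 30))
  expect_warning(zs <- zscore_standardize(train), "zero-variance")
  expect_identical(colnames(zs$train), "a")
  expect_identical(zs$dropped, "b")
})

test_that("stratified split honors per-class rounding and partitions the data", {
  y <- rep(c("GAP1", "GAP2"), each = 54)
  sp <- stratified_split(108, y, 0.7, seed = 3)
  expect_length(sp$train, 76)
  expect_length(sp$test, 32)
  expect_equal(as.integer(table(y[sp$train])), c(38L, 38L))
  expect_equal(as.integer(table(y[sp$test])), c(16L, 16L))
  expect_setequal(c(sp$train, sp$test), 1:108)
  expect_length(intersect(sp$train, sp$test), 0)

  sp2 <- stratified_split(20, rep(c("a", "b"), each = 10), 0.5, seed = 1)
  expect_equal(as.integer(table(rep(c("a", "b"), each = 10)[sp2$train])), c(5L, 5L))
})

test_that("a feature equal to the label is always confirmed by Boruta", {
  withr::with_seed(2, {
    X <- cbind(perfect = rep(c(0, 1), each = 25),
               matrix(rnorm(50 * 5), 50, 5,
                      dimnames = list(NULL, paste0("n", 1:5))))
  })
  y <- rep(c("a", "b"), each = 25)
  cfg <- selection_config(boruta_max_runs = 20, n_trees = 100, seed = 1)
  for (s in 1:3) {
    cfg$seed <- s
    expect_true("perfect" %in% boruta_select(X, y, cfg)$confirmed)
  }
  expect_error(boruta_select(X[c(1:3, 26:28), ], y[c(1:3, 26:28)], cfg),
               "at least 5")
})

test_that("Boruta recovers planted signal and rejects the bulk of noise", {
  cfg <- selection_config(boruta_max_runs = 30, n_trees = 100, seed = 1)
  all_recovered <- 0
  for (s in 1:10) {
    ft <- generate_feature_table(c(50, 50), n_informative = 5, n_noise = 95,
                                 effect_size_d = 2, seed = 100 + s)
    cfg$seed <- s
    bs <- boruta_select(as.matrix(ft[, -(1:2)]), ft$class, cfg)
    inf <- attr(ft, "informative_names")
    noise_rejected <- sum(!(setdiff(names(ft)[-(1:2)], inf) %in% bs$confirmed))
    if (all(inf %in% bs$confirmed) && noise_rejected >= 90)
      all_recovered <- all_recovered + 1
  }
  expect_gte(all_recovered, 9)
})

test_that("Boruta confirmations under permuted labels stay near the alpha level", {
  cfg <- selection_config(boruta_max_runs = 30, n_trees = 100, seed = 1)
  confs <- vapply(1:10, function(s) {
    ft <- generate_feature_table(c(30, 30), n_noise = 100, seed = 200 + s)
    y <- withr::with_seed(s, sample(ft$class))
    cfg$seed <- 500 + s
    length(boruta_select(as.matrix(ft[, -(1:2)]), y, cfg)$confirmed)
  }, numeric(1))
  expect_lte(mean(confs), 1)
})

test_that("correlation clustering separates copies from independents", {
  withr::with_seed(4, {
    base <- rnorm(60)
    X <- cbind(c1 = base, c2 = base, c3 = base, ind = rnorm(60))
  })
  cl <- correlation_clusters(X, 0.60)
  expect_equal(cl[["c1"]], cl[["c2"]])
  expect_equal(cl[["c1"]], cl[["c3"]])
  expect_false(cl[["ind"]] == cl[["c1"]])

  # r_threshold 1: only exact collinearity can merge
  cl2 <- correlation_clusters(cbind(X[, c("c1", "ind")],
                                    half = base + rnorm(60)), 1.0)
  expect_equal(length(unique(cl2)), 3L)
})

test_that("planted clusters are recovered at the study threshold", {
  ft <- generate_feature_table(c(40, 40), n_clusters = 3, cluster_size = 5,
                               n_noise = 2, seed = 6)
  cm <- attr(ft, "cluster_map")
  cl <- correlation_clusters(as.matrix(ft[, names(cm)[cm > 0]]), 0.60)
  multi <- table(cl)
  expect_gte(sum(multi >= 2), 3)
})

test_that("cluster representatives prefer signal and break ties lexicographically", {
  withr::with_seed(5, {
    y <- rep(c("a", "b"), each = 30)
    X <- cbind(signal = c(rnorm(30), rnorm(30, 3)), junk = rnorm(60))
  })
  expect_identical(cluster_representative(X, y, c("junk", "signal"), 200, 1),
                   "signal")
  expect_identical(cluster_representative(X, y, "junk"), "junk")
  # exchangeable copies: deterministic under a fixed seed
  X2 <- cbind(bb = X[, "signal"], aa = X[, "signal"])
  picks <- vapply(1:5, function(i) cluster_representative(X2, y, c("bb", "aa"),
                                                          100, 7),
                  character(1))
  expect_length(unique(picks), 1L)
})

test_that("no test-set moments leak into the selection pipeline (canary)", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  })
  y <- rep(c("a", "b"), each = 30)
  sp <- stratified_split(60, y, 0.7, seed = 2)
  zs1 <- zscore_standardize(X[sp$train, ], test = X[sp$test, ])
  # perturbing the test rows must not change the fitted moments or the
  # transformed training data
  X2 <- X; X2[sp$test, ] <- X2[sp$test, ] * 100 + 7
  zs2 <- zscore_standardize(X2[sp$train, ], test = X2[sp$test, ])
  expect_identical(zs1$center, zs2$center)
  expect_identical(zs1$train, zs2$train)
})
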