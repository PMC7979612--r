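test_that("GAP lookups reproduce hand-computed points and stages", {
  g <- gap_points("female", 58, fvc_pct = 98, dlco_pct = 79)
  expect_equal(g$points, 0L)
  expect_equal(g$stage, 1L)
  g2 <- gap_points("male", 68, fvc_pct = 65, dlco_pct = 40)
  expect_equal(g2$points, 5L)   # 1 + 2 + 1 + 1
  expect_equal(g2$stage, 2L)
  # cannot-perform DLCO scores 3
  g3 <- gap_points("male", 70, fvc_pct = 45, dlco_pct = NA)
  expect_equal(g3$points, 1L + 2L + 2L + 3L)
  expect_equal(g3$stage, 3L)
})

test_that("GAP points are monotone as each input worsens", {
  base <- list(gender = "female", age = 50, fvc = 90, dlco = 70)
  worsen <- list(
    gender = c("female", "male"),
    age = c(50, 62, 70),
    fvc = c(90, 70, 40),
    dlco = c(70, 50, 30)
  )
  for (var in names(worsen)) {
    pts <- vapply(worsen[[var]], function(val) {
      a <- base; a[[var]] <- val
      gap_points(a$gender, a$age, a$fvc, a$dlco)$points
    }, integer(1))
    expect_true(all(diff(pts) >= 1))
  }
  expect_error(gap_points("female", -4, 90, 70), "age")
  expect_error(gap_points("female", 50, 0, 70), "fvc")
})

test_that("coarseness score follows the six-lobe adjustment", {
  expect_equal(coarseness_score(c(1, 2, 3, 0, 0, 0)), 12)
  expect_equal(coarseness_score(rep(0, 6)), 0)
  expect_equal(coarseness_score(rep(4, 6)), 24)
  # equals six times the mean nonzero grade; invariant to zero-grade lobes
  g <- c(2, 3, 1)
  expect_equal(coarseness_score(g), 6 * mean(g[g > 0]))
  expect_equal(coarseness_score(c(g, 0, 0)), coarseness_score(g))
  expect_true(coarseness_score(c(4, 0, 0)) <= 24)
  expect_error(coarseness_score(c(1, 5)), "grades")
})

test_that("extent class dichotomizes strictly above 20%", {
  expect_equal(extent_class(0.19), "mild")
  expect_equal(extent_class(0.21), "severe")
  expect_equal(extent_class(0.20), "mild")
  expect_error(extent_class(1.2), "extent")
})

test_that("group comparison picks the right test per variable type", {
  grp <- rep(c("GAP1", "GAP2"), each = 20)
  tab <- data.frame(
    cont = c(rnorm(20), rnorm(20, 5)),
    cat = factor(rep(c("y", "n"), 20))
  )
  res <- group_compare(tab, grp)
  expect_equal(res$test[res$variable == "cont"], "wilcoxon_rank_sum")
  expect_lt(res$p_value[res$variable == "cont"], 0.001)

  # identical groups, large cells: chi-squared statistic 0, p = 1
  same <- data.frame(cat = factor(rep(c("y", "n"), 20)))
  res2 <- group_compare(same, grp)
  expect_equal(res2$test, "chi_squared")
  expect_equal(res2$p_value, 1)

  # identical small groups: expected cells < 5 trigger the exact test, p = 1
  grp_small <- rep(c("GAP1", "GAP2"), each = 4)
  small <- data.frame(cat = factor(rep(c("y", "n"), 4)))
  res3 <- group_compare(small, grp_small)
  expect_equal(res3$test, "fisher_exact")
  expect_equal(res3$p_value, 1)
})

test_that("a perfectly separated 2x2 table gives the hand-computed chi-squared", {
  grp <- rep(c("a", "b"), each = 20)
  x <- factor(rep(c("u", "v"), each = 20))
  res <- group_compare(data.frame(x = x), grp)
  expect_equal(res$test, "chi_squared")
  expect_equal(res$statistic, 40)
})

test_that("planted continuous shifts are detected with high power", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      tab <- data.frame(x = c(rnorm(50), rnorm(50, 2)))
    })
    grp <- rep(c("g1", "g2"), each = 50)
    group_compare(tab, grp)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
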