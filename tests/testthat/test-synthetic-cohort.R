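test_that("lesion-free phantom is plain parenchyma inside the HU clip range", {
  ph <- generate_volume(phantom_spec(shape_voxels = c(48, 48, 48),
                                     lesion_extent = 0, seed = 7))
  hu <- ph$volume$values[ph$mask]
  expect_true(all(hu >= -1000 & hu <= 100))
  expect_lt(abs(mean(hu) - (-850)), 15)
  expect_equal(ph$true_extent, 0)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantom_spec(shape_voxels = c(32, 32, 32), lesion_extent = 0.25,
                       lesion_mix = c(0.5, 0.3, 0.2), seed = 13)
  a <- generate_volume(spec)
  b <- generate_volume(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$lesion_map, b$lesion_map)
})

test_that("achieved lesion extent tracks the requested extent", {
  for (ext in c(0.1, 0.2, 0.4)) {
    ph <- generate_volume(phantom_spec(shape_voxels = c(100, 100, 100),
                                       lesion_extent = ext, seed = 3))
    measured <- sum(ph$lesion_map > 0) / sum(ph$mask)
    expect_lt(abs(measured - ext), 0.05)
    expect_equal(ph$true_extent, measured)
  }
})

test_that("lesion voxels form one connected region with the requested mix", {
  ph <- generate_volume(phantom_spec(shape_voxels = c(48, 48, 48),
                                     lesion_extent = 0.3,
                                     lesion_mix = c(0.5, 0.25, 0.25), seed = 5))
  lab <- ildradiomics:::label_components_26(ph$lesion_map > 0)
  expect_equal(max(lab), 1L)
  n <- sum(ph$lesion_map > 0)
  expect_lt(abs(sum(ph$lesion_map == 1L) / n - 0.5), 0.05)
})

test_that("degenerate phantom shapes are rejected", {
  expect_error(phantom_spec(shape_voxels = c(8, 32, 32)), "16")
  expect_error(phantom_spec(lesion_extent = 1.2), "lesion_extent")
  expect_error(phantom_spec(lesion_mix = c(0.7, 0.2, 0.2)), "sum")
})

test_that("cohort sizes, labels and stage consistency match the generator contract", {
  coh <- generate_cohort(54, 6, seed = 1)
  expect_equal(nrow(coh$clinical), 60)
  expect_equal(sum(coh$clinical$gap_stage_true == 1), 54)
  # every record re-stages to its own label
  restaged <- vapply(seq_len(60), function(i) {
    r <- coh$clinical[i, ]
    gap_points(r$gender, r$age, r$fvc_pct, r$dlco_pct)$stage
  }, integer(1))
  expect_identical(restaged, coh$clinical$gap_stage_true)

  coh2 <- generate_cohort(0, 5, seed = 2)
  expect_equal(nrow(coh2$clinical), 5)
  expect_true(all(coh2$clinical$gap_stage_true == 2))
})

test_that("cohort pulmonary-function means converge to the group parameters", {
  coh <- generate_cohort(200, 200, seed = 2)
  g1 <- coh$clinical[coh$clinical$gap_stage_true == 1, ]
  g2 <- coh$clinical[coh$clinical$gap_stage_true == 2, ]
  expect_lt(abs(mean(g1$fev1_pct) - 93), 3)
  expect_gt(mean(g2$lesion_extent), mean(g1$lesion_extent))
  expect_gt(stats::median(g2$age), stats::median(g1$age))
})

test_that("cohort generation is deterministic and round-trips through CSV", {
  a <- generate_cohort(10, 4, seed = 9)
  b <- generate_cohort(10, 4, seed = 9)
  expect_identical(a$clinical, b$clinical)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(a, path)
  back <- read_cohort_csv(path)
  expect_equal(back$fvc_pct, a$clinical$fvc_pct, tolerance = 1e-8)
})

test_that("planted feature tables have the advertised structure", {
  ft <- generate_feature_table(c(40, 40), n_informative = 2, n_noise = 5,
                               n_clusters = 3, cluster_size = 5, seed = 6)
  cm <- attr(ft, "cluster_map")
  X <- as.matrix(ft[, -(1:2)])
  # intra-cluster correlation >= 0.8 by construction (sample slack 0.6)
  for (k in 1:3) {
    mem <- names(cm)[cm == k]
    cc <- stats::cor(X[, mem])
    expect_gt(min(cc[upper.tri(cc)]), 0.6)
  }
  # nuisance clusters recovered at the pipeline threshold
  cl <- correlation_clusters(X[, names(cm)[cm > 0]], 0.60)
  expect_gte(length(unique(cl)), 3)
  expect_identical(ft, generate_feature_table(c(40, 40), n_informative = 2,
                                              n_noise = 5, n_clusters = 3,
                                              cluster_size = 5, seed = 6))
})

test_that("null informative features are calibrated (type-I error near alpha)", {
  # d = 0: the two-sample t-test on the "informative" feature rejects at
  # about the nominal 5% rate
  rej <- vapply(1:500, function(s) {
    ft <- generate_feature_table(c(15, 15), n_informative = 1,
                                 effect_size_d = 0, seed = s)
    stats::t.test(ft$inf_01 ~ ft$class)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
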