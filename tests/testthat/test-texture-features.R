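const_dz <- function(n = 4) {
  v <- ct_volume(array(-500, c(n, n, n)), c(1, 1, 1))
  discretize(v, array(TRUE, c(n, n, n)), 35, anchor_hu = NULL)
}

test_that("GLCM of a constant region is a single certain cell", {
  P <- build_glcm(const_dz(), "merged")
  expect_equal(sum(P), 1)
  expect_equal(P[1, 1], 1)
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["homogenity"]), 1)
  expect_equal(unname(f["jointEnergy"]), 1)
})

test_that("two-voxel GLCM example evaluates by hand", {
  lev <- array(c(1L, 2L), c(2, 1, 1))
  P <- build_glcm(as_dz(lev), "merged")
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["homogenity"]), 0.5)
  expect_equal(unname(f["jointEnergy"]), 0.5)
})

test_that("merged GLCM equals the renormalized sum of directional counts", {
  lev <- random_level_volume(c(5, 5, 5), 4, seed = 11)
  dz <- as_dz(lev)
  dirs <- build_glcm(dz, "averaged")
  counts <- ildradiomics:::glcm_count_matrices(lev, dz$Ng)
  merged <- Reduce(`+`, counts)
  expect_equal(build_glcm(dz, "merged"), merged / sum(merged))
  expect_length(dirs, 13)
})

test_that("NGTDM features are zero on constants and single voxels", {
  f <- ngtdm_features(const_dz())
  expect_equal(unname(f["neighContrast"]), 0)
  expect_equal(unname(f["coarseness"]), 1e12)
  lev <- array(0L, c(3, 3, 3)); lev[2, 2, 2] <- 1L
  expect_true(all(ngtdm_features(as_dz(lev)) == 0))
})

test_that("NGTDM on a two-level checkerboard matches the brute-force oracle", {
  lev <- array(0L, c(2, 2, 2))
  lev[] <- as.integer((slice.index(lev, 1) + slice.index(lev, 2) +
                         slice.index(lev, 3)) %% 2 + 1)
  expect_equal(ngtdm_features(as_dz(lev)), oracle_ngtdm_features(lev, 2),
               tolerance = 1e-12)
})

test_that("run-length hand examples evaluate correctly", {
  lev <- array(c(1L, 1L, 2L), c(3, 1, 1))
  runs <- oracle_glrlm_runs(lev, c(1, 0, 0))
  expect_equal(nrow(runs), 2)
  st <- oracle_glrlm_features(runs, 2, 3)
  expect_equal(unname(st["shortRunEmph"]), 0.625)
  # constant line of N voxels: run percentage 1/N in the line direction
  levN <- array(1L, c(7, 1, 1))
  stN <- oracle_glrlm_features(oracle_glrlm_runs(levN, c(1, 0, 0)), 1, 7)
  expect_equal(unname(stN["runPercentage"]), 1 / 7)
})

test_that("size-zone hand examples evaluate correctly", {
  lv <- array(0L, c(7, 1, 1)); lv[1:2] <- 1L; lv[5:7] <- 1L
  f <- glszm_features(as_dz(lv))
  expect_equal(unname(f["sizeVar"]), 0.25)
  fc <- glszm_features(const_dz())
  expect_equal(unname(fc["smallZoneEmph"]), 1 / 64^2)
})

test_that("intensity features handle constants and degenerate spreads", {
  v <- ct_volume(array(-500, c(4, 4, 4)), c(1, 1, 1))
  f <- intensity_features(v, array(TRUE, c(4, 4, 4)))
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["range"]), 0)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["cov"]), 0)
})

test_that("box-counting dimension recovers solids and planes", {
  cube <- array(TRUE, c(64, 64, 64))
  expect_lt(abs(fractal_dimension(cube) - 3), 0.3)
  plane <- array(FALSE, c(64, 64, 64)); plane[, , 32] <- TRUE
  expect_lt(abs(fractal_dimension(plane) - 2), 0.3)
})

test_that("shape features recover cube volume and sphere sphericity", {
  m <- array(FALSE, c(14, 14, 14)); m[3:12, 3:12, 3:12] <- TRUE
  f <- shape_features(m, c(2, 2, 2))
  expect_equal(unname(f["volume_ml"]), 8)

  d <- c(41, 41, 41)
  co <- arrayInd(seq_len(prod(d)), d)
  sph <- array(sqrt(rowSums(sweep(co, 2, c(21, 21, 21))^2)) <= 15, d)
  fs <- shape_features(sph, c(1, 1, 1))
  expect_gte(unname(fs["sphericity"]), 0.95)
  expect_equal(unname(fs["maxDiameter3D"]), 30)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(unname(shape_features(single, 1)["maxDiameter3D"]), 0)
})

test_that("merged-direction texture features are invariant to axis permutation", {
  lev <- random_level_volume(c(6, 5, 4), 5, seed = 21)
  perm <- aperm(lev, c(3, 1, 2))
  for (build in list(
    function(l) glcm_features(build_glcm(as_dz(l), "merged")),
    function(l) glrlm_features(as_dz(l), "merged"),
    function(l) glszm_features(as_dz(l)),
    function(l) ngtdm_features(as_dz(l))
  )) {
    expect_equal(build(lev), build(perm), tolerance = 1e-10)
  }
})

test_that("NGTDM contrast increases monotonically with lesion extent", {
  extents <- seq(0, 0.4, length.out = 10)
  vals <- vapply(extents, function(e) {
    ph <- generate_volume(phantom_spec(shape_voxels = c(40, 40, 40),
                                       spacing_mm = c(2, 2, 2),
                                       lesion_extent = e, seed = 31))
    dz <- discretize(ph$volume, ph$mask, 35)
    unname(ngtdm_features(dz)["neighContrast"])
  }, numeric(1))
  expect_gt(stats::cor(extents, vals, method = "spearman"), 0.9)
})
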