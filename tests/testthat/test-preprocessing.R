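test_that("HU-window masking keeps exactly the in-window voxels", {
  v <- ct_volume(array(-500, c(6, 6, 6)), c(1, 1, 1))
  expect_true(all(mask_lung(v)))

  vals <- array(-1000, c(3, 3, 3))
  vals[2, 2, 2] <- -800
  vals[1, 1, 1] <- 0
  v2 <- ct_volume(vals, c(1, 1, 1))
  m <- mask_lung(v2, largest_component = FALSE)
  expect_identical(which(m), which(vals == -800))
})

test_that("only the largest 26-connected blob survives component filtering", {
  vals <- array(-1000, c(20, 20, 20))
  vals[2:11, 2:11, 2:11] <- -500          # 1000-voxel blob
  vals[15:16, 15:16, 15:16] <- -500       # 8-voxel blob, not 26-adjacent
  v <- ct_volume(vals, c(1, 1, 1))
  m <- mask_lung(v)
  expect_equal(sum(m), 1000)
  expect_false(m[15, 15, 15])
  # oracle: flood fill finds two components before filtering
  zones <- oracle_glszm_zones(array(as.integer(vals == -500), dim(vals)))
  expect_equal(sort(zones[, 2]), c(8, 1000))
})

test_that("an all-outside-window volume raises an empty-mask error", {
  v <- ct_volume(array(0, c(5, 5, 5)), c(1, 1, 1))
  expect_error(mask_lung(v), "empty mask")
})

test_that("resampling reproduces constants and linear ramps exactly", {
  v <- ct_volume(array(-700, c(9, 9, 9)), c(1, 1, 1))
  out <- resample_isotropic(v, target_mm = 2)
  expect_true(all(abs(out$values - (-700)) < 1e-12))
  expect_equal(out$spacing_mm, c(2, 2, 2))

  ramp <- ct_volume(array(rep(1:9, times = 81), c(9, 9, 9)), c(1, 1, 1))
  out2 <- resample_isotropic(ramp, target_mm = 2)
  expect_equal(out2$values[, 1, 1], c(1, 3, 5, 7, 9))
})

test_that("resampled grid size follows the extent/spacing arithmetic", {
  v <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  m <- array(TRUE, c(4, 4, 4))
  out <- resample_isotropic(v, m, target_mm = 2)
  expect_equal(dim(out$volume$values), c(2L, 2L, 2L))
  expect_equal(dim(out$mask), c(2L, 2L, 2L))
  expect_error(resample_isotropic(v, target_mm = 10), "smaller than 2")
})

test_that("mask voxel count is approximately preserved by 1 mm -> 2 mm resampling", {
  ph <- generate_volume(phantom_spec(shape_voxels = c(64, 64, 64),
                                     spacing_mm = c(1, 1, 1), seed = 2))
  rs <- resample_isotropic(ph$volume, ph$mask, 2)
  vol_in <- sum(ph$mask) * 1
  vol_out <- sum(rs$mask) * 8
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.05)
})

test_that("masking and resampling nearly commute on phantoms", {
  ph <- generate_volume(phantom_spec(shape_voxels = c(48, 48, 48),
                                     spacing_mm = c(1, 1, 1),
                                     lesion_extent = 0.2, seed = 4))
  m1 <- mask_lung(ph$volume)
  a <- resample_isotropic(ph$volume, m1, 2)$mask
  b_vol <- resample_isotropic(ph$volume, target_mm = 2)
  b <- mask_lung(b_vol)
  agree <- mean(a == b)
  expect_gt(agree, 0.97)
})

test_that("discretization follows the anchored floor formula", {
  m <- array(TRUE, c(4, 1, 1))
  v <- ct_volume(array(c(-950, -916, -915, -940), c(4, 1, 1)), c(1, 1, 1))
  d35 <- discretize(v, m, 35)
  expect_identical(as.integer(d35$levels), c(1L, 1L, 2L, 1L))
  d10 <- discretize(v, m, 10)
  expect_identical(as.integer(d10$levels[c(1, 4)]), c(1L, 2L))
  # a constant region anchored at its own minimum collapses to one level
  dc <- discretize(ct_volume(array(-500, c(3, 3, 3)), 1),
                   array(TRUE, c(3, 3, 3)), 35, anchor_hu = NULL)
  expect_equal(dc$Ng, 1L)
  expect_true(all(dc$levels == 1L))
  # anchored at the window edge the same region sits at a higher level
  dw <- discretize(ct_volume(array(-500, c(3, 3, 3)), 1),
                   array(TRUE, c(3, 3, 3)), 35)
  expect_equal(dw$Ng, 13L)
})

test_that("discretization is monotone in HU", {
  set.seed(1)
  hu <- sort(runif(100, -1000, 100))
  v <- ct_volume(array(hu, c(100, 1, 1)), c(1, 1, 1))
  d <- discretize(v, array(TRUE, c(100, 1, 1)), 35)
  expect_true(all(diff(as.integer(d$levels)) >= 0))
})
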