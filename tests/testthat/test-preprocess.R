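test_that("identity resampling reproduces the input grid", {
  set.seed(2)
  arr <- array(sample(-900L:200L, 12^3, TRUE), c(12, 12, 12))
  msk <- array(FALSE, c(12, 12, 12))
  msk[4:9, 4:9, 4:9] <- TRUE
  v <- ct_volume(arr, spacing = rep(0.77, 3))
  m <- segmentation_mask(msk, spacing = rep(0.77, 3))
  out <- resample_isotropic(v, m, 0.77)
  expect_equal(dim(out$volume$voxels), dim(arr))
  expect_equal(out$volume$voxels, arr * 1.0, tolerance = 1e-8)
  expect_equal(out$mask$voxels, msk)
})

test_that("halving the spacing doubles each grid dimension", {
  arr <- array(0L, c(10, 12, 14))
  msk <- array(FALSE, dim(arr)); msk[4:6, 5:7, 6:8] <- TRUE
  v <- ct_volume(arr, spacing = rep(1.54, 3))
  m <- segmentation_mask(msk, spacing = rep(1.54, 3))
  out <- resample_isotropic(v, m, 0.77)
  expect_true(all(abs(dim(out$volume$voxels) - 2 * dim(arr)) <= 1))
})

test_that("a sphere mask keeps its analytic volume through resampling", {
  sp <- c(0.5, 0.5, 2.0)
  d <- c(60, 60, 16)
  ax <- ((seq_len(d[1]) - 1) - (d[1] - 1) / 2) * sp[1]
  ay <- ((seq_len(d[2]) - 1) - (d[2] - 1) / 2) * sp[2]
  az <- ((seq_len(d[3]) - 1) - (d[3] - 1) / 2) * sp[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  msk <- r2 <= 10^2
  v <- ct_volume(array(0L, d), sp)
  m <- segmentation_mask(msk, sp)
  out <- resample_isotropic(v, m, 0.77)
  vol_mm3 <- sum(out$mask$voxels) * 0.77^3
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
  # shape-based interpolation preserves the topology of a convex mask
  expect_equal(oracle_label3d_count(out$mask$voxels), 1L)
})

test_that("misaligned or empty masks are rejected", {
  v <- ct_volume(array(0L, c(8, 8, 8)), rep(1, 3))
  m_big <- segmentation_mask(array(TRUE, c(9, 8, 8)), rep(1, 3))
  expect_error(resample_isotropic(v, m_big, 1), class = "bettimap_alignment")
  m_empty <- segmentation_mask(array(FALSE, c(8, 8, 8)), rep(1, 3))
  expect_error(resample_isotropic(v, m_empty, 1), class = "bettimap_degenerate")
})

test_that("max-area slice selection is deterministic with low-index ties", {
  mk <- function(areas) {
    arr <- array(FALSE, c(10, 10, length(areas)))
    for (k in seq_along(areas)) if (areas[k] > 0) arr[seq_len(areas[k]), 1, k] <- TRUE
    segmentation_mask(arr, rep(1, 3))
  }
  expect_equal(select_max_area_slice(mk(c(0, 3, 7, 2))), 3L) # unique max
  expect_equal(select_max_area_slice(mk(c(5, 9, 9))), 2L)    # tie -> lowest
  set.seed(4)
  m <- segmentation_mask(array(runif(6 * 6 * 9) < 0.3, c(6, 6, 9)), rep(1, 3))
  areas <- apply(m$voxels, 3, sum)
  expect_equal(areas[select_max_area_slice(m)], max(areas))
  # inserting an empty slice never changes the selected physical slice
  aug <- array(FALSE, c(6, 6, 10))
  aug[, , 2:10] <- m$voxels
  expect_equal(select_max_area_slice(segmentation_mask(aug, rep(1, 3))),
               select_max_area_slice(m) + 1L)
  expect_error(select_max_area_slice(mk(c(0, 0))), class = "bettimap_degenerate")
})

test_that("requantization maps the window linearly with clipping", {
  cfg <- quant_preset("mediastinal", 8)
  roi1 <- matrix(TRUE, 1, 1)
  q <- function(v) requantize(matrix(v, 1, 1), roi1, cfg)$image[1, 1]
  expect_equal(q(-150), 0L)
  expect_equal(q(250), 255L)
  expect_equal(q(50), 128L)   # floor((200/400) * 256)
  expect_equal(q(-650), 0L)   # clipped below the window
  expect_equal(q(900), 255L)  # clipped above
  # monotone non-decreasing in HU
  vals <- sort(runif(50, -400, 500))
  g <- requantize(matrix(vals, 1), matrix(TRUE, 1, 50), cfg)$image
  expect_true(all(diff(as.numeric(g)) >= 0))
  # idempotent on values re-expressed in HU at the level centres
  cfg5 <- quant_preset("lung", 5)
  lv <- 0:31
  hu <- cfg5$hu_low + (lv + 0.5) / 32 * (cfg5$hu_high - cfg5$hu_low)
  g2 <- requantize(matrix(hu, 1), matrix(TRUE, 1, 32), cfg5)$image
  expect_equal(as.integer(g2), lv)
})

test_that("quantization configs validate their window and bit depth", {
  expect_error(quant_config(100, -100, 8), class = "bettimap_param")
  expect_error(quant_config(-100, 100, 9), class = "bettimap_param")
  expect_equal(quant_preset("full", 6)$hu_low, -1000)
  expect_equal(nrow(quant_presets()), 12)
})

test_that("preprocess_case yields an analyzable quantized slice", {
  ph <- generate_case(phantom_spec(seed = 13))
  qs <- preprocess_case(ph$volume, ph$mask, quant_preset("mediastinal", 5))
  expect_s3_class(qs, "quantized_slice")
  expect_true(all(qs$image >= 0 & qs$image <= 31))
  expect_gt(sum(qs$roi), 50)
  expect_equal(qs$pixel_size, 0.77)
})
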