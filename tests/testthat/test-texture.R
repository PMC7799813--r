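test_that("histogram features handle constant and symmetric inputs", {
  f <- histogram_features(rep(4, 25))
  expect_equal(unname(f["Histogram_Variance"]), 0)
  expect_equal(unname(f["Histogram_Entropy"]), 0)
  expect_equal(unname(f["Histogram_Range"]), 0)
  expect_equal(unname(f["Histogram_Uniformity"]), 1)
  expect_equal(unname(f["Histogram_Skewness"]), 0)
  sym <- c(-3, -1, 0, 1, 3) + 10
  expect_equal(unname(histogram_features(sym)["Histogram_Skewness"]), 0)
  expect_error(histogram_features(numeric(0)), class = "bettimap_degenerate")
})

test_that("histogram features match direct recomputation on random data", {
  set.seed(14)
  v <- sample(0:20, 100, TRUE)
  f <- histogram_features(v)
  m <- mean(v); m2 <- mean((v - m)^2)
  p <- as.numeric(table(v)) / length(v)
  expect_equal(unname(f["Histogram_Mean"]), m)
  expect_equal(unname(f["Histogram_Variance"]), m2)
  expect_equal(unname(f["Histogram_Skewness"]), mean((v - m)^3) / m2^1.5)
  expect_equal(unname(f["Histogram_Kurtosis"]), mean((v - m)^4) / m2^2)
  expect_equal(unname(f["Histogram_Energy"]), sum(v^2))
  expect_equal(unname(f["Histogram_Entropy"]), -sum(p * log2(p)))
  expect_equal(unname(f["Histogram_Uniformity"]), sum(p^2))
  expect_equal(unname(f["Histogram_Minimum"]), min(v))
  expect_equal(unname(f["Histogram_Maximum"]), max(v))
  expect_equal(unname(f["Histogram_Median"]), median(v))
  expect_equal(unname(f["Histogram_P10"]), quantile(v, .1, names = FALSE))
  expect_equal(unname(f["Histogram_P90"]), quantile(v, .9, names = FALSE))
  expect_equal(unname(f["Histogram_IQR"]),
               quantile(v, .75, names = FALSE) - quantile(v, .25, names = FALSE))
  expect_equal(unname(f["Histogram_Range"]), max(v) - min(v))
})

test_that("GLCM features behave on degenerate and structured inputs", {
  roi <- matrix(TRUE, 4, 4)
  f <- glcm_features(matrix(5L, 4, 4), roi)
  expect_equal(unname(f["GLCM_Energy"]), 1)
  expect_equal(unname(f["GLCM_Contrast"]), 0)
  expect_equal(unname(f["GLCM_Dissimilarity"]), 0)
  # two-level checkerboard along one direction: all pairs differ by one level
  chk <- matrix(rep(c(0L, 1L), 8), 4, 4)      # rows alternate 0/1
  cfg <- texture_config(glcm_directions = 90)  # vertical pairs in image terms
  f2 <- glcm_features(chk, roi, cfg)
  expect_equal(unname(f2["GLCM_Contrast"]), 1) # squared level difference
  expect_equal(unname(f2["GLCM_Energy"]), 0.5)
  expect_error(glcm_features(matrix(1L, 1, 1), matrix(TRUE, 1, 1)),
               class = "bettimap_degenerate")
})

test_that("GLCM probabilities match brute-force pair enumeration", {
  set.seed(15)
  map <- matrix(sample(0L:5L, 100, TRUE), 10)
  roi <- random_binary(10, 10, 0.8)
  cfg <- texture_config()
  d <- bettimap:::discretize_map(map, roi, cfg)
  P <- bettimap:::glcm_probability(d$lev, d$G, cfg$glcm_dirs)
  expect_equal(sum(P), 1, tolerance = 1e-9)
  expect_true(all(P >= 0))
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  Po <- matrix(0, d$G, d$G); used <- 0
  for (dd in dirs) {
    M <- oracle_glcm_counts(d$lev, d$G, dd[1], dd[2])
    if (sum(M) > 0) { Po <- Po + M / sum(M); used <- used + 1 }
  }
  expect_equal(P, Po / used, tolerance = 1e-12)
  f <- glcm_features(map, roi)
  expect_equal(unname(f["GLCM_Energy"]), sum((Po / used)^2))
})

test_that("GLRLM features match single-run arithmetic and the run oracle", {
  row4 <- matrix(2L, 1, 4)
  cfg0 <- texture_config(glrlm_directions = 0)
  f <- glrlm_features(row4, matrix(TRUE, 1, 4), cfg0)
  expect_equal(unname(f["GLRLM_RP"]), 1 / 4)
  expect_equal(unname(f["GLRLM_LRE"]), 16)
  alt <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  f2 <- glrlm_features(alt, matrix(TRUE, 1, 4), cfg0)
  expect_equal(unname(f2["GLRLM_RP"]), 1)
  expect_equal(unname(f2["GLRLM_SRE"]), 1)
  set.seed(16)
  map <- matrix(sample(0L:4L, 81, TRUE), 9)
  roi <- random_binary(9, 9, 0.85)
  d <- bettimap:::discretize_map(map, roi, texture_config())
  M <- bettimap:::cpp_glrlm(d$lev, d$G, 0:3)
  steps <- list(c(0, 1), c(1, -1), c(1, 0), c(1, 1)) # walk vectors, one per direction
  Mo <- matrix(0, d$G, max(dim(d$lev)))
  for (st in steps) {
    runs <- oracle_runs(d$lev, st[1], st[2])
    for (k in seq_len(nrow(runs))) Mo[runs[k, 1], runs[k, 2]] <- Mo[runs[k, 1], runs[k, 2]] + 1
  }
  expect_equal(unname(M), unname(Mo))
})

test_that("GLSZM features match hand-built matrices and the zone oracle", {
  roi9 <- matrix(TRUE, 3, 3)
  f <- glszm_features(matrix(4L, 3, 3), roi9)
  expect_equal(unname(f["GLSZM_ZP"]), 1 / 9)
  # two separated constant patches of the same level, sizes 3 and 5
  m <- matrix(0L, 3, 6)
  m[1, 1:3] <- 2L
  m[3, 2:6] <- 2L
  roi <- m > 0
  f2 <- glszm_features(m, roi, texture_config())
  expect_equal(unname(f2["GLSZM_GLN"]), 2)        # both zones share one level: 2^2/2
  expect_equal(unname(f2["GLSZM_SAE"]), mean(c(1 / 9, 1 / 25)))
  expect_equal(unname(f2["GLSZM_ZP"]), 2 / 8)
  set.seed(17)
  map <- matrix(sample(0L:3L, 64, TRUE), 8)
  roiR <- random_binary(8, 8, 0.8)
  d <- bettimap:::discretize_map(map, roiR, texture_config())
  Z <- bettimap:::cpp_zone_sizes(d$lev)
  Zo <- oracle_zones(d$lev)
  expect_equal(sort(paste(Z[, 1], Z[, 2])), sort(paste(Zo[, 1], Zo[, 2])))
})

test_that("NGTDM features follow the documented conventions and oracle", {
  roi <- matrix(TRUE, 4, 4)
  f <- ngtdm_features(matrix(3L, 4, 4), roi)
  expect_equal(unname(f["NGTDM_Contrast"]), 0)
  expect_equal(unname(f["NGTDM_Busyness"]), 0)
  expect_equal(unname(f["NGTDM_Coarseness"]), 1e6)
  # single bright pixel in a flat 5x5 map, hand computation
  m <- matrix(0L, 5, 5); m[3, 3] <- 2L
  d <- bettimap:::discretize_map(m, matrix(TRUE, 5, 5), texture_config())
  acc <- bettimap:::cpp_ngtdm(d$lev, d$G)
  o <- oracle_ngtdm(d$lev, d$G)
  expect_equal(acc$n, o$n)
  expect_equal(acc$s, o$s, tolerance = 1e-12)
  # the bright pixel (level 3) sits on 8 level-1 neighbours: s_3 = 2
  expect_equal(acc$s[3], 2)
  set.seed(18)
  mr <- matrix(sample(0L:4L, 49, TRUE), 7)
  roiR <- random_binary(7, 7, 0.8)
  dr <- bettimap:::discretize_map(mr, roiR, texture_config())
  accr <- bettimap:::cpp_ngtdm(dr$lev, dr$G)
  or <- oracle_ngtdm(dr$lev, dr$G)
  expect_equal(accr$n, or$n)
  expect_equal(accr$s, or$s, tolerance = 1e-12)
})

test_that("feature vectors have canonical lengths and names", {
  set.seed(19)
  img <- matrix(sample(0L:255L, 24 * 24, TRUE), 24)
  qs8 <- make_qslice(img, bits = 8L)
  st <- bn_maps(qs8, bn_map_config(7, 3))
  rg <- roi_on_map_grid(qs8$roi, bn_map_config(7, 3))
  fv <- extract_bn_features(st, rg)
  expect_length(fv, 2^8 * 3 * 54)
  expect_true("b0_GLCM_Energy_45" %in% names(fv))
  expect_true("b1/b0_GLSZM_ZSN_104" %in% names(fv))
  expect_true("b1_GLCM_SumAverage_122" %in% names(fv))
  expect_true("b0_GLRLM_LRLGE_97" %in% names(fv))
  expect_false(any(duplicated(names(fv))))
  qs5 <- make_qslice(matrix(sample(0L:31L, 144, TRUE), 12), bits = 5L)
  oi <- extract_oi_features(qs5)
  expect_length(oi, 54)
  expect_named(oi[1], "Histogram_Mean")
  wd <- extract_wd_features(qs5)
  expect_length(wd, 216)
  expect_true("GLSZM_LGZE_LL" %in% names(wd))
  # constant ROI: histogram variance present and zero for OI
  cst <- make_qslice(matrix(7L, 12, 12), bits = 5L)
  expect_equal(unname(extract_oi_features(cst)["Histogram_Variance"]), 0)
})

test_that("OI extraction equals calling the family functions directly", {
  set.seed(20)
  img <- matrix(sample(0L:31L, 100, TRUE), 10)
  roi <- random_binary(10, 10, 0.9)
  qs <- make_qslice(img, roi, bits = 5L)
  f <- extract_oi_features(qs)
  expect_equal(f[15:23], glcm_features(img, roi))
  expect_equal(f[24:36], glrlm_features(img, roi))
  expect_equal(f[37:49], glszm_features(img, roi))
  expect_equal(f[50:54], ngtdm_features(img, roi))
  expect_equal(f[1:14], histogram_features(img[roi]))
})

test_that("order-preserving relabeling leaves structural features unchanged", {
  set.seed(22)
  map <- matrix(sample(0L:5L, 100, TRUE), 10)
  roi <- matrix(TRUE, 10, 10)
  re <- map * 2L + 3L
  keep <- c("GLRLM_GLN", "GLRLM_RLN", "GLRLM_RP")
  expect_equal(glrlm_features(map, roi)[keep], glrlm_features(re, roi)[keep])
  keepz <- c("GLSZM_GLN", "GLSZM_ZSN", "GLSZM_ZP")
  expect_equal(glszm_features(map, roi)[keepz], glszm_features(re, roi)[keepz])
})

test_that("feature extraction is deterministic", {
  set.seed(23)
  img <- matrix(sample(0L:31L, 225, TRUE), 15)
  qs <- make_qslice(img, bits = 5L)
  expect_identical(extract_oi_features(qs), extract_oi_features(qs))
  expect_identical(extract_wd_features(qs), extract_wd_features(qs))
})
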