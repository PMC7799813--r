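#' Texture extraction configuration
#'
#' Controls how maps are discretized for the texture matrices and which
#' directions are used. Integer-valued maps (Betti counts, re-quantized
#' images) keep their values as gray levels directly — `G = max value + 1`
#' levels, preserving count semantics — capped at `g_cap` levels with linear
#' re-binning above the cap. Real-valued maps (`b1/b0` ratios, wavelet
#' subbands) are linearly binned into `n_bins_real` levels over their ROI
#' range. Texture formulas index levels 1..G.
#'
#' @param n_bins_real Bins for real-valued maps (default 32).
#' @param g_cap Gray-level cap for integer maps (default 64).
#' @param glcm_directions,glrlm_directions Subsets of `c(0, 45, 90, 135)`
#'   (degrees).
#' @return A `texture_config` list.
#' @export
texture_config <- function(n_bins_real = 32, g_cap = 64,
                           glcm_directions = c(0, 45, 90, 135),
                           glrlm_directions = c(0, 45, 90, 135)) {
  all_dirs <- c(0, 45, 90, 135)
  if (n_bins_real < 2 || g_cap < 2) stop_param("need at least 2 gray levels")
  if (!all(glcm_directions %in% all_dirs) || length(glcm_directions) == 0)
    stop_param("glcm_directions must be a non-empty subset of 0/45/90/135")
  if (!all(glrlm_directions %in% all_dirs) || length(glrlm_directions) == 0)
    stop_param("glrlm_directions must be a non-empty subset of 0/45/90/135")
  structure(list(
    n_bins_real = as.integer(n_bins_real), g_cap = as.integer(g_cap),
    glcm_dirs = match(glcm_directions, all_dirs),
    glrlm_dirs = match(glrlm_directions, all_dirs)
  ), class = "texture_config")
}

# Discretize a map to levels 1..G inside the ROI, 0 outside. Integer-valued
# non-negative maps keep value + 1 as their level (capped); anything else is
# equal-width binned over the ROI range.
discretize_map <- function(map, roi, cfg) {
  map <- as.matrix(map)
  roi <- as.matrix(roi)
  if (!identical(dim(map), dim(roi))) stop_param("map and roi shapes differ")
  vals <- map[roi]
  if (length(vals) == 0) stop_degenerate("empty ROI")
  lev <- matrix(0L, nrow(map), ncol(map))
  integerish <- all(abs(vals - round(vals)) < 1e-9) && min(vals) >= 0
  if (integerish) {
    vmax <- max(round(vals))
    if (vmax + 1 <= cfg$g_cap) {
      G <- as.integer(vmax + 1)
      lev[roi] <- as.integer(round(vals)) + 1L
    } else {
      G <- cfg$g_cap
      lev[roi] <- pmin(G, as.integer(floor(round(vals) * G / (vmax + 1))) + 1L)
    }
  } else {
    rng <- range(vals)
    if (rng[1] == rng[2]) {
      G <- 1L
      lev[roi] <- 1L
    } else {
      G <- cfg$n_bins_real
      lev[roi] <- pmin(G, as.integer(floor((vals - rng[1]) / (rng[2] - rng[1]) * G)) + 1L)
    }
  }
  list(lev = lev, G = G)
}

#' Histogram features of a value set
#'
#' The fourteen first-order features: Mean, Variance (population), Skewness
#' and Kurtosis (`m3/m2^1.5`, `m4/m2^2`, both 0 for constant input),
#' Energy (sum of squares), Entropy and Uniformity (over discrete values
#' when the input is integer-valued, over 32 equal-width bins otherwise;
#' log base 2), Minimum, 10th percentile, Median, 90th percentile, Maximum,
#' Range and interquartile range.
#'
#' @param values Numeric vector (the in-ROI map values); must be non-empty.
#' @return Named numeric vector of length 14, names `Histogram_*`.
#' @examples
#' histogram_features(c(1, 2, 2, 3))
#' @export
histogram_features <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_degenerate("no values")
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 else 0
  p <- value_probabilities(values)
  q <- quantile(values, c(.1, .25, .5, .75, .9), names = FALSE)
  out <- c(
    Mean = m, Variance = m2, Skewness = skew, Kurtosis = kurt,
    Energy = sum(values^2),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    Minimum = min(values), P10 = q[1], Median = q[3], P90 = q[5],
    Maximum = max(values), Range = max(values) - min(values),
    IQR = q[4] - q[2],
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("Histogram_", names(out))
  out
}

value_probabilities <- function(values, n_bins = 32L) {
  if (all(abs(values - round(values)) < 1e-9)) {
    tab <- table(round(values))
  } else if (min(values) == max(values)) {
    return(1)
  } else {
    b <- pmin(n_bins, floor((values - min(values)) /
                              (max(values) - min(values)) * n_bins) + 1)
    tab <- tabulate(b, n_bins)
  }
  p <- as.numeric(tab) / length(values)
  p[p > 0]
}

glcm_probability <- function(lev, G, dirs) {
  counts <- cpp_glcm_counts(lev, G)
  P <- matrix(0, G, G)
  used <- 0
  for (d in dirs) {
    slab <- counts[, , d]
    s <- sum(slab)
    if (s > 0) {
      P <- P + slab / s
      used <- used + 1
    }
  }
  if (used == 0) stop_degenerate("fewer than one valid pixel pair for the GLCM")
  P / used
}

glcm_features_impl <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  c(
    GLCM_Energy = sum(P^2),
    GLCM_Contrast = sum((i - j)^2 * P),
    GLCM_Entropy = -sum(P[P > 0] * log2(P[P > 0])),
    GLCM_Homogeneity = sum(P / (1 + abs(i - j))),
    GLCM_Correlation = corr,
    GLCM_SumAverage = sum((i + j) * P),
    GLCM_Variance = sig2,
    GLCM_Dissimilarity = sum(abs(i - j) * P),
    GLCM_AutoCorrelation = sum(i * j * P)
  )
}

#' Gray-level co-occurrence features
#'
#' Nine features from the symmetric distance-1 co-occurrence matrix, each
#' direction's matrix normalized and then averaged over the configured
#' directions. Only pixel pairs with both members inside the ROI count.
#' Correlation is 0 by convention when the gray-level variance is 0.
#'
#' @param map 2-D numeric matrix (a BN map, quantized image or subband).
#' @param roi Logical matrix, same shape.
#' @param cfg A [texture_config()].
#' @return Named numeric vector (`GLCM_*`).
#' @export
glcm_features <- function(map, roi, cfg = texture_config()) {
  d <- discretize_map(map, roi, cfg)
  glcm_features_impl(glcm_probability(d$lev, d$G, cfg$glcm_dirs))
}

glrlm_features_impl <- function(M, n_pixels, n_dirs) {
  keep <- which(colSums(M) > 0)
  if (length(keep) == 0) stop_degenerate("no runs in ROI")
  M <- M[, seq_len(max(keep)), drop = FALSE]
  Nr <- sum(M)
  p <- M / Nr
  i <- matrix(seq_len(nrow(M)), nrow(M), ncol(M))
  j <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(
    GLRLM_SRE = sum(M / j^2) / Nr,
    GLRLM_LRE = sum(M * j^2) / Nr,
    GLRLM_GLN = sum(rowSums(M)^2) / Nr,
    GLRLM_RLN = sum(colSums(M)^2) / Nr,
    GLRLM_RP = Nr / (n_pixels * n_dirs),
    GLRLM_LGRE = sum(M / i^2) / Nr,
    GLRLM_HGRE = sum(M * i^2) / Nr,
    GLRLM_SRLGE = sum(M / (i^2 * j^2)) / Nr,
    GLRLM_SRHGE = sum(M * i^2 / j^2) / Nr,
    GLRLM_LRLGE = sum(M * j^2 / i^2) / Nr,
    GLRLM_LRHGE = sum(M * i^2 * j^2) / Nr,
    GLRLM_GLV = sum(p * (i - mu_i)^2),
    GLRLM_RLV = sum(p * (j - mu_j)^2)
  )
}

#' Gray-level run-length features
#'
#' Thirteen features from the run-length matrix with runs collected over the
#' configured directions and summed into one matrix before feature
#' computation. Out-of-ROI pixels break runs. Run percentage divides by
#' (ROI pixels x number of directions) so that a fully homogeneous ROI in a
#' single direction with runs of length L gives RP = 1/L.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`GLRLM_*`).
#' @export
glrlm_features <- function(map, roi, cfg = texture_config()) {
  d <- discretize_map(map, roi, cfg)
  M <- cpp_glrlm(d$lev, d$G, cfg$glrlm_dirs - 1L)
  glrlm_features_impl(M, sum(as.matrix(roi)), length(cfg$glrlm_dirs))
}

glszm_features_impl <- function(level, size, n_pixels) {
  Nz <- length(level)
  i <- level
  j <- size
  mu_i <- mean(i)
  mu_j <- mean(j)
  gl_sum <- tapply(rep(1, Nz), i, sum)
  sz_sum <- tapply(rep(1, Nz), j, sum)
  c(
    GLSZM_SAE = mean(1 / j^2),
    GLSZM_LAE = mean(j^2),
    GLSZM_GLN = sum(gl_sum^2) / Nz,
    GLSZM_ZSN = sum(sz_sum^2) / Nz,
    GLSZM_ZP = Nz / n_pixels,
    GLSZM_LGZE = mean(1 / i^2),
    GLSZM_HGZE = mean(i^2),
    GLSZM_SZLGE = mean(1 / (i^2 * j^2)),
    GLSZM_SZHGE = mean(i^2 / j^2),
    GLSZM_LZLGE = mean(j^2 / i^2),
    GLSZM_LZHGE = mean(i^2 * j^2),
    GLSZM_GLV = mean((i - mu_i)^2),
    GLSZM_ZSV = mean((j - mu_j)^2)
  )
}

#' Gray-level size-zone features
#'
#' Thirteen features over the zones of the ROI, a zone being an 8-connected
#' component of equal gray level. Size-zone features are direction-free.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`GLSZM_*`).
#' @export
glszm_features <- function(map, roi, cfg = texture_config()) {
  d <- discretize_map(map, roi, cfg)
  Z <- cpp_zone_sizes(d$lev)
  glszm_features_impl(Z[, 1], Z[, 2], sum(as.matrix(roi)))
}

ngtdm_features_impl <- function(n_i, s_i, coarseness_cap = 1e6) {
  N <- sum(n_i)
  if (N == 0) stop_degenerate("no ROI pixel has an in-ROI neighbour")
  p <- n_i / N
  idx <- which(p > 0)
  Ngp <- length(idx)
  ii <- matrix(idx, Ngp, Ngp)
  jj <- t(ii)
  pi_ <- p[idx]
  pim <- matrix(pi_, Ngp, Ngp)
  pjm <- t(pim)
  sim <- matrix(s_i[idx], Ngp, Ngp)
  sjm <- t(sim)
  den_coar <- sum(p * s_i)
  coarseness <- if (den_coar > 0) 1 / den_coar else coarseness_cap
  contrast <- if (Ngp > 1)
    sum(pim * pjm * (ii - jj)^2) / (Ngp * (Ngp - 1)) * sum(s_i) / N else 0
  den_busy <- sum(abs(ii * pim - jj * pjm))
  busyness <- if (den_busy > 0) sum(p * s_i) / den_busy else 0
  complexity <- sum(abs(ii - jj) * (pim * sim + pjm * sjm) / (pim + pjm)) / N
  den_str <- sum(s_i)
  strength <- if (den_str > 0) sum((pim + pjm) * (ii - jj)^2) / den_str else 0
  c(NGTDM_Coarseness = coarseness, NGTDM_Contrast = contrast,
    NGTDM_Busyness = busyness, NGTDM_Complexity = complexity,
    NGTDM_Strength = strength)
}

#' Neighbourhood gray-tone difference features
#'
#' Five features from the NGTDM with 3x3 neighbourhoods restricted to
#' in-ROI pixels. Zero-denominator conventions: Busyness and Strength are 0;
#' Coarseness is capped at 1e6 when every neighbourhood difference is 0.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector (`NGTDM_*`).
#' @export
ngtdm_features <- function(map, roi, cfg = texture_config()) {
  d <- discretize_map(map, roi, cfg)
  acc <- cpp_ngtdm(d$lev, d$G)
  ngtdm_features_impl(acc$n, acc$s)
}

# All 54 features of one map restricted to an ROI; shared discretization.
features_54 <- function(map, roi, cfg = texture_config()) {
  roi <- as.matrix(roi)
  map <- as.matrix(map)
  hist_f <- histogram_features(map[roi])
  d <- discretize_map(map, roi, cfg)
  np <- sum(roi)
  glcm_f <- glcm_features_impl(glcm_probability(d$lev, d$G, cfg$glcm_dirs))
  M <- cpp_glrlm(d$lev, d$G, cfg$glrlm_dirs - 1L)
  glrlm_f <- glrlm_features_impl(M, np, length(cfg$glrlm_dirs))
  Z <- cpp_zone_sizes(d$lev)
  glszm_f <- glszm_features_impl(Z[, 1], Z[, 2], np)
  acc <- cpp_ngtdm(d$lev, d$G)
  ngtdm_f <- ngtdm_features_impl(acc$n, acc$s)
  c(hist_f, glcm_f, glrlm_f, glszm_f, ngtdm_f)
}

#' Extract the Betti-number feature vector of a case
#'
#' Applies the 54-feature set to every map of the stack restricted to the
#' ROI on the map grid: `2^q` thresholds x 3 map families x 54 features.
#' Feature names follow `{b0|b1|b1/b0}_{family}_{Feature}_{threshold}`, e.g.
#' `b0_GLCM_Energy_45`.
#'
#' @param stack A [bn_maps()] result.
#' @param roi_grid Logical matrix over the map grid (see
#'   [roi_on_map_grid()]); must be non-empty.
#' @param cfg A [texture_config()].
#' @return Named numeric vector of length `2^q * 3 * 54`.
#' @export
extract_bn_features <- function(stack, roi_grid, cfg = texture_config()) {
  if (!inherits(stack, "bn_map_stack")) stop_param("`stack` must be a bn_map_stack")
  roi_grid <- as.matrix(roi_grid)
  if (!any(roi_grid)) stop_degenerate("empty ROI on the map grid")
  nt <- length(stack$thresholds)
  sources <- c("b0", "b1", "b1/b0")
  arrays <- list(stack$b0, stack$b1, stack$ratio)
  out <- vector("list", nt * 3L)
  pos <- 0L
  for (ti in seq_len(nt)) {
    t <- stack$thresholds[ti]
    for (si in 1:3) {
      f <- features_54(arrays[[si]][, , ti], roi_grid, cfg)
      names(f) <- paste0(sources[si], "_", names(f), "_", t)
      pos <- pos + 1L
      out[[pos]] <- f
    }
  }
  unlist(out)
}

#' Extract original-image (OI) features of a case
#'
#' The 54-feature set applied to the re-quantized slice within its ROI,
#' named `{family}_{Feature}`.
#'
#' @param slice A `quantized_slice`.
#' @param cfg A [texture_config()].
#' @return Named numeric vector of length 54.
#' @export
extract_oi_features <- function(slice, cfg = texture_config()) {
  if (!inherits(slice, "quantized_slice")) stop_param("`slice` must be a quantized_slice")
  if (!any(slice$roi)) stop_degenerate("empty ROI")
  features_54(slice$image, slice$roi, cfg)
}

#' Extract wavelet-decomposition (WD) features of a case
#'
#' The 54-feature set applied to each of the four stationary Coiflet-1
#' subbands of the re-quantized slice (undecimated, so the ROI applies
#' unchanged), named `{family}_{Feature}_{LL|LH|HL|HH}`.
#'
#' @inheritParams extract_oi_features
#' @return Named numeric vector of length 216.
#' @export
extract_wd_features <- function(slice, cfg = texture_config()) {
  if (!inherits(slice, "quantized_slice")) stop_param("`slice` must be a quantized_slice")
  if (!any(slice$roi)) stop_degenerate("empty ROI")
  sb <- wavelet_subbands(slice$image)
  out <- purrr::imap(sb, function(band, nm) {
    f <- features_54(band, slice$roi, cfg)
    names(f) <- paste0(names(f), "_", nm)
    f
  })
  unlist(unname(out))
}
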