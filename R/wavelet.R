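# Coiflet-1 analysis filters (orthonormal; the synthesis pair is the
# time-reverse). Coefficients frozen from the standard published filter bank.
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# Index extension: 0-based index i into 0..n-1 under half-point symmetric
# reflection (x[-1] = x[0]) or periodic wrap.
extend_index <- function(i, n, mode) {
  if (mode == "periodic") return(i %% n)
  repeat {
    neg <- i < 0
    i[neg] <- -1L - i[neg]
    big <- i >= n
    i[big] <- 2L * n - 1L - i[big]
    if (!any(i < 0 | i >= n)) return(i)
  }
}

# Undecimated correlation of each column of X with filter h:
# y[i] = sum_k h[k] x[i + k - offset], offset centers the 6-tap filter.
swt_filter_cols <- function(X, h, mode) {
  n <- nrow(X)
  off <- 2L
  Y <- matrix(0, n, ncol(X))
  for (k in seq_along(h)) {
    idx <- extend_index(seq_len(n) - 1L + (k - 1L) - off, n, mode)
    Y <- Y + h[k] * X[idx + 1L, , drop = FALSE]
  }
  Y
}

# Adjoint of swt_filter_cols (used for reconstruction):
# y[i] = sum_k h[k] x[i - k + offset], with matching extension.
swt_adjoint_cols <- function(X, h, mode) {
  n <- nrow(X)
  off <- 2L
  Y <- matrix(0, n, ncol(X))
  for (k in seq_along(h)) {
    idx <- extend_index(seq_len(n) - 1L - (k - 1L) + off, n, mode)
    Y <- Y + h[k] * X[idx + 1L, , drop = FALSE]
  }
  Y
}

#' Single-level stationary Coiflet-1 wavelet decomposition
#'
#' Undecimated (stationary) 2-D transform: the Coiflet-1 low- and high-pass
#' filters are applied along x (rows of the image matrix) and y (columns)
#' in all four combinations, without downsampling, so every subband has the
#' shape of the input and the ROI applies pixel-for-pixel. Boundaries are
#' extended symmetrically by default; `mode = "periodic"` gives the
#' circular variant for which the transform satisfies perfect
#' reconstruction via [inverse_wavelet_subbands()].
#'
#' @param image 2-D numeric matrix, at least 6 pixels per axis.
#' @param mode Boundary extension, `"symmetric"` (default) or `"periodic"`.
#' @return Named list of matrices `LL`, `LH`, `HL`, `HH`. The first letter
#'   is the filter applied along x, the second along y.
#' @examples
#' sb <- wavelet_subbands(matrix(rnorm(144), 12))
#' names(sb)
#' @export
wavelet_subbands <- function(image, mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  image <- as.matrix(image) * 1.0
  if (nrow(image) < 6 || ncol(image) < 6)
    stop_degenerate("image smaller than the wavelet filter support")
  lx <- swt_filter_cols(image, coif1_lo, mode)          # low-pass along x
  hx <- swt_filter_cols(image, coif1_hi, mode)          # high-pass along x
  list(
    LL = t(swt_filter_cols(t(lx), coif1_lo, mode)),
    LH = t(swt_filter_cols(t(lx), coif1_hi, mode)),
    HL = t(swt_filter_cols(t(hx), coif1_lo, mode)),
    HH = t(swt_filter_cols(t(hx), coif1_hi, mode))
  )
}

#' @rdname wavelet_subbands
#' @param subbands A list as returned by [wavelet_subbands()].
#' @export
inverse_wavelet_subbands <- function(subbands, mode = c("periodic", "symmetric")) {
  mode <- match.arg(mode)
  rec_y <- function(M, h) t(swt_adjoint_cols(t(M), h, mode))
  ll <- rec_y(subbands$LL, coif1_lo)
  lh <- rec_y(subbands$LH, coif1_hi)
  hl <- rec_y(subbands$HL, coif1_lo)
  hh <- rec_y(subbands$HH, coif1_hi)
  x <- swt_adjoint_cols(ll + lh, coif1_lo, mode) +
    swt_adjoint_cols(hl + hh, coif1_hi, mode)
  x / 4
}
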