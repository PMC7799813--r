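#' Betti-map computation configuration
#'
#' Sliding-window geometry for Betti-number maps: a square `kernel` x
#' `kernel` window advanced by `stride` pixels. Only fully contained windows
#' are evaluated (no padding, which would inject artificial components).
#' Connectivity is fixed at foreground-8 / background-4, the standard
#' digital-topology pairing.
#'
#' @param kernel Odd window side in pixels, >= 5 (the canonical search set is
#'   5, 7, 9, 11).
#' @param stride Window shift in pixels, 1..5.
#' @return A `bn_map_config` list.
#' @examples
#' bn_map_config(kernel = 7, stride = 1)
#' @export
bn_map_config <- function(kernel = 7, stride = 1) {
  if (!is.numeric(kernel) || kernel < 5 || kernel %% 2 != 1)
    stop_param("`kernel` must be an odd integer >= 5")
  if (!is.numeric(stride) || stride < 1 || stride > 5)
    stop_param("`stride` must be in 1..5")
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride)),
            class = "bn_map_config")
}

#' Binarize a quantized image at a threshold
#'
#' Foreground is `pixel >= t`, so `t = 0` yields the all-foreground image
#' and `t = 2^q - 1` keeps only the top gray level.
#'
#' @param image Integer matrix of gray levels, or a `quantized_slice`.
#' @param t Threshold in `[0, 2^q - 1]`.
#' @return Logical matrix.
#' @examples
#' binarize(matrix(0:3, 2), 2)
#' @export
binarize <- function(image, t) {
  if (inherits(image, "quantized_slice")) {
    if (t < 0 || t > 2^image$bits - 1)
      stop_param("threshold outside [0, 2^q - 1]")
    image <- image$image
  } else if (t < 0) {
    stop_param("threshold must be >= 0")
  }
  as.matrix(image) >= t
}

#' Betti numbers of a binary window
#'
#' `b0` is the number of 8-connected foreground components; `b1` the number
#' of enclosed holes, i.e. 4-connected background components that do not
#' touch the window border. An empty window is (0, 0).
#'
#' @param window Logical (or 0/1) matrix.
#' @return Named integer vector `c(b0 = , b1 = )`.
#' @examples
#' ring <- matrix(TRUE, 5, 5); ring[3, 3] <- FALSE
#' betti_numbers(ring) # one component, one hole
#' @export
betti_numbers <- function(window) {
  window <- as.matrix(window)
  if (length(window) == 0) stop_param("empty window")
  storage.mode(window) <- "logical"
  cpp_betti(window)
}

#' Compute the Betti-number map stack of a quantized slice
#'
#' For every threshold `t` in `0 .. 2^q - 1` the slice is binarized at `t`
#' and a k x k window slides over it with the configured stride; each map
#' cell holds the Betti numbers of its window. Three maps per threshold are
#' kept: `b0`, `b1` and the ratio `b1/b0` (0 where `b0 = 0`), for
#' `2^q x 3` maps in total.
#'
#' @param slice A `quantized_slice` (see [requantize()]); both slice
#'   dimensions must be at least `kernel`.
#' @param config A [bn_map_config()].
#' @return A `bn_map_stack`: list with 3-D arrays `b0`, `b1`, `ratio` of dim
#'   (row windows, col windows, thresholds), the `thresholds` vector, the
#'   config, and window-center coordinates `center_rows`, `center_cols` in
#'   slice pixel indices.
#' @examples
#' ph <- generate_case(phantom_spec(seed = 5))
#' qs <- preprocess_case(ph$volume, ph$mask, quant_preset("mediastinal", 5))
#' st <- bn_maps(qs, bn_map_config(7, 2))
#' dim(st$b1)
#' @export
bn_maps <- function(slice, config = bn_map_config()) {
  if (!inherits(slice, "quantized_slice")) stop_param("`slice` must be a quantized_slice")
  k <- config$kernel
  s <- config$stride
  img <- slice$image
  if (nrow(img) < k || ncol(img) < k)
    stop_degenerate("slice smaller than the kernel")
  thresholds <- 0:(2^slice$bits - 1)
  maps <- cpp_bn_maps(img, k, s, thresholds)
  ratio <- maps$b1 / ifelse(maps$b0 == 0, NA, maps$b0)
  ratio[is.na(ratio)] <- 0
  mr <- dim(maps$b0)[1]
  mc <- dim(maps$b0)[2]
  structure(list(
    b0 = maps$b0, b1 = maps$b1, ratio = ratio,
    thresholds = thresholds, kernel = k, stride = s,
    center_rows = (seq_len(mr) - 1L) * s + (k + 1L) %/% 2L,
    center_cols = (seq_len(mc) - 1L) * s + (k + 1L) %/% 2L,
    pixel_size = slice$pixel_size
  ), class = "bn_map_stack")
}

#' @export
print.bn_map_stack <- function(x, ...) {
  cat("<bn_map_stack> ", length(x$thresholds), " thresholds x 3 maps of ",
      dim(x$b0)[1], " x ", dim(x$b0)[2], " windows (kernel ", x$kernel,
      ", stride ", x$stride, ")\n", sep = "")
  invisible(x)
}

#' Transfer an ROI from slice pixels to the BN map grid
#'
#' A map cell is inside the ROI iff its window's center pixel is inside the
#' slice ROI.
#'
#' @param roi Logical matrix over slice pixels.
#' @param config The [bn_map_config()] used for the maps.
#' @return Logical matrix over the map grid.
#' @export
roi_on_map_grid <- function(roi, config = bn_map_config()) {
  roi <- as.matrix(roi)
  k <- config$kernel
  s <- config$stride
  if (nrow(roi) < k || ncol(roi) < k)
    stop_degenerate("roi smaller than the kernel")
  mr <- (nrow(roi) - k) %/% s + 1L
  mc <- (ncol(roi) - k) %/% s + 1L
  cr <- (seq_len(mr) - 1L) * s + (k + 1L) %/% 2L
  cc <- (seq_len(mc) - 1L) * s + (k + 1L) %/% 2L
  matrix(roi[cr, cc], mr, mc)
}

#' Plot maps from a BN map stack
#'
#' Raster panels of one map family (`b0`, `b1` or `ratio`) at a selection of
#' thresholds.
#'
#' @param object A `bn_map_stack`.
#' @param map One of `"b0"`, `"b1"`, `"ratio"`.
#' @param thresholds Thresholds to show; defaults to four spread over the range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_map_stack <- function(object, map = c("b1", "b0", "ratio"),
                                  thresholds = NULL, ...) {
  map <- match.arg(map)
  if (is.null(thresholds))
    thresholds <- unique(round(quantile(object$thresholds, c(.2, .4, .6, .8))))
  arr <- object[[map]]
  df <- purrr::map_dfr(thresholds, function(t) {
    sl <- arr[, , match(t, object$thresholds)]
    tibble(threshold = t,
           row = rep(seq_len(nrow(sl)), ncol(sl)),
           col = rep(seq_len(ncol(sl)), each = nrow(sl)),
           value = as.vector(sl))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~threshold, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = map) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
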