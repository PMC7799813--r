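#' Quantization configuration and HU window presets
#'
#' Re-quantization maps a HU window linearly onto `2^bits` gray levels.
#' Three named windows are provided: `"full"` (-1000, 1500) HU, `"lung"`
#' (-1350, 150) HU and `"mediastinal"` (-150, 250) HU.
#'
#' @param hu_low,hu_high HU window bounds, `hu_low < hu_high`.
#' @param bits Bit depth q; one of 5, 6, 7, 8.
#' @param window Preset name for [quant_preset()].
#' @return A `quant_config` list with elements `hu_low`, `hu_high`, `bits`.
#' @examples
#' quant_preset("mediastinal", bits = 8)
#' @export
quant_config <- function(hu_low, hu_high, bits) {
  if (!is.numeric(hu_low) || !is.numeric(hu_high) || hu_low >= hu_high)
    stop_param("need hu_low < hu_high")
  if (!bits %in% c(5, 6, 7, 8)) stop_param("`bits` must be one of 5, 6, 7, 8")
  structure(list(hu_low = hu_low, hu_high = hu_high, bits = as.integer(bits)),
            class = "quant_config")
}

#' @rdname quant_config
#' @export
quant_preset <- function(window = c("mediastinal", "lung", "full"), bits = 8) {
  window <- match.arg(window)
  w <- switch(window, full = c(-1000, 1500), lung = c(-1350, 150),
              mediastinal = c(-150, 250))
  quant_config(w[1], w[2], bits)
}

#' @rdname quant_config
#' @export
quant_presets <- function() {
  tidyr::expand_grid(window = c("full", "lung", "mediastinal"), bits = 5:8)
}

# Interpolation matrix mapping samples at old index positions (0-based,
# physical x = i * old_sp) onto targets x = j * new_sp, Keys cubic
# convolution kernel (a = -1/2), border handled by index clamping. The
# kernel interpolates exactly at the knots, so identity grids reproduce the
# input bitwise up to float round-off.
keys_weight <- function(d) {
  ad <- abs(d)
  ifelse(ad <= 1, 1.5 * ad^3 - 2.5 * ad^2 + 1,
         ifelse(ad < 2, -0.5 * ad^3 + 2.5 * ad^2 - 4 * ad + 2, 0))
}

interp_matrix <- function(n_old, old_sp, n_new, new_sp) {
  A <- matrix(0, n_new, n_old)
  u <- (seq_len(n_new) - 1) * new_sp / old_sp # target in old index units
  base <- floor(u)
  for (k in -1:2) {
    idx <- base + k
    w <- keys_weight(u - idx)
    idx <- pmin(pmax(idx, 0), n_old - 1)
    A[cbind(seq_len(n_new), idx + 1)] <- A[cbind(seq_len(n_new), idx + 1)] + w
  }
  A
}

apply_axis <- function(arr, A, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- A %*% matrix(x, dp[1])
  dim(y) <- c(nrow(A), dp[2], dp[3])
  aperm(y, order(perm))
}

resample_grid <- function(arr, spacing, iso_mm) {
  d <- dim(arr)
  n_new <- pmax(1L, as.integer(round(d * spacing / iso_mm)))
  for (ax in 1:3) {
    A <- interp_matrix(d[ax], spacing[ax], n_new[ax], iso_mm)
    arr <- apply_axis(arr, A, ax)
  }
  arr
}

signed_distance <- function(mask_arr, spacing) {
  if (!any(mask_arr)) stop_degenerate("mask has no foreground voxels")
  dims <- as.integer(dim(mask_arr))
  if (all(mask_arr)) return(array(-1e6, dims)) # no boundary: deep inside everywhere
  d_fg <- sqrt(cpp_sq_edt3d(as.logical(mask_arr), dims, spacing))
  d_bg <- sqrt(cpp_sq_edt3d(!as.logical(mask_arr), dims, spacing))
  array(d_fg - d_bg, dims)
}

#' Resample a CT volume and its mask to an isotropic grid
#'
#' Intensities are resampled with cubic (Keys) interpolation; the mask is
#' resampled shape-based: its signed Euclidean distance field (negative
#' inside) is interpolated cubically onto the target grid and re-thresholded
#' at zero. The output grid has `round(dim * spacing / iso_mm)` voxels per
#' axis, sampled at physical positions `j * iso_mm` from the first voxel.
#'
#' @param volume A [ct_volume()].
#' @param mask A [segmentation_mask()] on the same grid.
#' @param iso_mm Target isotropic voxel size in mm; default 0.77.
#' @return A list with elements `volume` and `mask` on the isotropic grid.
#' @examples
#' ph <- generate_case(phantom_spec(seed = 7))
#' iso <- resample_isotropic(ph$volume, ph$mask)
#' iso$volume$spacing
#' @export
resample_isotropic <- function(volume, mask, iso_mm = 0.77) {
  if (!inherits(volume, "ct_volume") || !inherits(mask, "segmentation_mask"))
    stop_param("need a ct_volume and a segmentation_mask")
  if (!is.numeric(iso_mm) || iso_mm <= 0) stop_param("`iso_mm` must be > 0")
  if (!same_grid(volume, mask))
    stop_align("mask grid does not match the volume grid")
  if (!any(mask$voxels)) stop_degenerate("mask has no foreground voxels")
  vox <- resample_grid(volume$voxels * 1.0, volume$spacing, iso_mm)
  sdf <- signed_distance(mask$voxels, mask$spacing)
  sdf_new <- resample_grid(sdf, mask$spacing, iso_mm)
  m_new <- sdf_new < 0
  if (!any(m_new)) stop_degenerate("mask vanished after resampling")
  sp <- rep(iso_mm, 3)
  list(volume = ct_volume(vox, sp, volume$origin),
       mask = segmentation_mask(m_new, sp, mask$origin))
}

#' Select the axial slice with maximal ROI area
#'
#' Returns the (1-based) index along the third axis whose slice has the
#' largest foreground pixel count; ties break to the lowest index.
#'
#' @param mask A [segmentation_mask()] with at least one foreground voxel.
#' @return Integer slice index.
#' @export
select_max_area_slice <- function(mask) {
  if (!inherits(mask, "segmentation_mask")) stop_param("need a segmentation_mask")
  areas <- apply(mask$voxels, 3, sum)
  if (all(areas == 0)) stop_degenerate("mask has no foreground voxels")
  which.max(areas)
}

#' Re-quantize a HU slice to q bits
#'
#' Values are clipped to the HU window, then mapped by
#' `g = floor((v - hu_low) / (hu_high - hu_low) * 2^q)` with `v = hu_high`
#' assigned the top level `2^q - 1`. The map is monotone non-decreasing in HU.
#'
#' @param slice_hu 2-D numeric matrix of HU values.
#' @param roi 2-D logical matrix, same shape.
#' @param cfg A [quant_config()].
#' @param pixel_size Isotropic pixel size in mm (carried along for metadata).
#' @return A `quantized_slice`: list with `image` (integer matrix in
#'   `[0, 2^q - 1]`), `roi`, `pixel_size`, `bits`.
#' @examples
#' q <- requantize(matrix(c(-150, 50, 250, 400), 2), matrix(TRUE, 2, 2),
#'                 quant_preset("mediastinal", 8))
#' q$image
#' @export
requantize <- function(slice_hu, roi, cfg, pixel_size = NA_real_) {
  if (!inherits(cfg, "quant_config")) stop_param("`cfg` must be a quant_config")
  slice_hu <- as.matrix(slice_hu)
  roi <- as.matrix(roi)
  if (!identical(dim(slice_hu), dim(roi))) stop_param("image and roi shapes differ")
  g_max <- 2L^cfg$bits - 1L
  v <- pmin(pmax(slice_hu, cfg$hu_low), cfg$hu_high)
  g <- floor((v - cfg$hu_low) / (cfg$hu_high - cfg$hu_low) * 2^cfg$bits)
  g <- pmin(g, g_max)
  img <- matrix(as.integer(g), nrow(slice_hu))
  structure(list(image = img, roi = roi & TRUE, pixel_size = pixel_size,
                 bits = cfg$bits),
            class = "quantized_slice")
}

#' @export
print.quantized_slice <- function(x, ...) {
  cat("<quantized_slice> ", nrow(x$image), " x ", ncol(x$image), " pixels, ",
      x$bits, "-bit, ", sum(x$roi), " ROI pixels\n", sep = "")
  invisible(x)
}

#' Preprocess one case to an analysis-ready quantized slice
#'
#' Resamples volume and mask to an isotropic grid, picks the axial slice
#' with the largest ROI area (selection happens after resampling), and
#' re-quantizes it under the given HU window. This is the standard front end
#' for feature extraction.
#'
#' @inheritParams resample_isotropic
#' @inheritParams requantize
#' @return A `quantized_slice`.
#' @examples
#' ph <- generate_case(phantom_spec(seed = 3))
#' qs <- preprocess_case(ph$volume, ph$mask, quant_preset("mediastinal", 5))
#' qs
#' @export
preprocess_case <- function(volume, mask, cfg, iso_mm = 0.77) {
  iso <- resample_isotropic(volume, mask, iso_mm)
  k <- select_max_area_slice(iso$mask)
  requantize(iso$volume$voxels[, , k], iso$mask$voxels[, , k], cfg,
             pixel_size = iso_mm)
}
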