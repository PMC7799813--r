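#' Synthetic CT tumor phantom specification
#'
#' Describes one synthetic case: a bright solid ellipsoidal lesion in a dark
#' lung background on an anisotropic grid, with smooth Gaussian-blob
#' heterogeneity, a Poisson number of low-intensity spherical "holes"
#' (hazy, ground-glass-like depressions whose density carries the class
#' signal), and additive Gaussian noise. Holes are placed fully interior to
#' the tumor and, so that the 2-D analysis slice sees them, within a thin
#' axial slab around the tumor equator.
#'
#' Defaults (chosen once as the package's reference conditions): a 40 x 40
#' x 24 grid at 0.7 x 0.7 x 2.0 mm — deliberately anisotropic so the
#' isotropic resampling front end is always exercised — a 9 x 9 x 12 mm
#' tumor at 40 HU over a -800 HU background, holes of radius 1.2-2.2 mm
#' depressed by 550 HU, and 15 HU noise.
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing Voxel spacing in mm.
#' @param radii_mm Tumor ellipsoid semi-axes in mm.
#' @param tumor_hu,background_hu Base intensities.
#' @param blob_n,blob_amp_hu,blob_scale_mm Heterogeneity blobs: count,
#'   amplitude range (drawn uniform in ±amp), Gaussian scale.
#' @param hole_lambda Poisson mean of the hole count.
#' @param hole_radius_mm Length-2 range of hole radii. Holes are kept small
#'   relative to the analysis windows so each survives thresholding as a
#'   genuine enclosed hole (a b1 structure) rather than merging into a large
#'   cavity.
#' @param hole_depth_hu HU depression inside holes.
#' @param hole_slab_mm Half-thickness of the axial slab holes are placed in.
#' @param hole_min_gap_mm Minimum tissue gap between hole surfaces, so holes
#'   never coalesce and every hole keeps a solid ring of tumor around it.
#' @param noise_sd_hu Additive Gaussian noise SD.
#' @param seed Integer seed fixing all randomness of the case.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 24), spacing = c(0.7, 0.7, 2.0),
                         radii_mm = c(9, 9, 12), tumor_hu = 40,
                         background_hu = -800, blob_n = 6, blob_amp_hu = 50,
                         blob_scale_mm = 3.5, hole_lambda = 4,
                         hole_radius_mm = c(0.8, 1.6), hole_depth_hu = 550,
                         hole_slab_mm = 2.0, hole_min_gap_mm = 1.0,
                         noise_sd_hu = 15, seed = 1) {
  if (any(radii_mm <= 0)) stop_param("tumor radii must be positive")
  if (hole_lambda < 0) stop_param("hole_lambda must be >= 0")
  if (any(2 * radii_mm >= grid_shape * spacing))
    stop_param("tumor larger than the grid")
  structure(as.list(environment()), class = "phantom_spec")
}

# Pairwise-sum field over the grid: f(x) + g(y) + h(z) as a 3-D array.
axis_field <- function(fx, fy, fz) {
  outer(outer(fx, fy, "+"), fz, "+")
}

#' Generate one synthetic case
#'
#' Deterministic given `spec$seed`: the same spec yields identical volumes.
#' With zero blobs, holes and noise the tumor interior is exactly the base
#' HU.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([ct_volume()]), `mask`
#'   ([segmentation_mask()]) and `meta` (realized hole count and geometry).
#' @examples
#' case <- generate_case(phantom_spec(seed = 42))
#' case$meta$n_holes
#' @export
generate_case <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_param("`spec` must be a phantom_spec")
  d <- spec$grid_shape
  sp <- spec$spacing
  ax <- ((seq_len(d[1]) - 1) - (d[1] - 1) / 2) * sp[1]
  ay <- ((seq_len(d[2]) - 1) - (d[2] - 1) / 2) * sp[2]
  az <- ((seq_len(d[3]) - 1) - (d[3] - 1) / 2) * sp[3]
  r <- spec$radii_mm
  ell <- axis_field(ax^2 / r[1]^2, ay^2 / r[2]^2, az^2 / r[3]^2)
  mask <- ell <= 1
  vol <- array(spec$background_hu, d)
  vol[mask] <- spec$tumor_hu
  withr::with_seed(spec$seed, {
    if (spec$blob_n > 0 && spec$blob_amp_hu > 0) {
      for (b in seq_len(spec$blob_n)) {
        ctr <- sample_in_ellipsoid(r * 0.7)
        amp <- runif(1, -spec$blob_amp_hu, spec$blob_amp_hu)
        d2 <- axis_field((ax - ctr[1])^2, (ay - ctr[2])^2, (az - ctr[3])^2)
        bump <- amp * exp(-d2 / (2 * spec$blob_scale_mm^2))
        vol[mask] <- vol[mask] + bump[mask]
      }
    }
    n_holes <- rpois(1, spec$hole_lambda)
    centers <- matrix(numeric(0), 0, 4)
    if (n_holes > 0) {
      hole <- array(FALSE, d)
      for (h in seq_len(n_holes)) {
        hr <- runif(1, spec$hole_radius_mm[1], spec$hole_radius_mm[2])
        ctr <- sample_hole_center(r, hr + 0.5, spec$hole_slab_mm,
                                  centers, hr + spec$hole_min_gap_mm)
        if (any(is.na(ctr))) next
        d2 <- axis_field((ax - ctr[1])^2, (ay - ctr[2])^2, (az - ctr[3])^2)
        hole <- hole | (d2 <= hr^2)
        centers <- rbind(centers, c(ctr, hr))
      }
      vol[hole & mask] <- vol[hole & mask] - spec$hole_depth_hu
    }
    if (spec$noise_sd_hu > 0)
      vol <- vol + rnorm(length(vol), 0, spec$noise_sd_hu)
  })
  vol <- round(vol)
  storage.mode(vol) <- "integer"
  list(volume = ct_volume(vol, sp),
       mask = segmentation_mask(mask, sp),
       meta = list(n_holes = nrow(centers), holes = centers, seed = spec$seed))
}

# Uniform draw inside an origin-centred ellipsoid (rejection from the box).
sample_in_ellipsoid <- function(radii) {
  for (i in 1:200) {
    p <- runif(3, -1, 1) * radii
    if (sum((p / radii)^2) <= 1) return(p)
  }
  c(0, 0, 0)
}

# Hole centre: inside the tumor shrunk by `margin` (so the hole is fully
# interior), within |z| <= slab_mm, and at least `gap_plus_r` + prior radius
# away from every previously placed hole centre (so holes never merge).
# NA if no admissible position is found.
sample_hole_center <- function(radii, margin, slab_mm, placed, gap_plus_r) {
  shr <- radii - margin
  if (any(shr <= 0)) return(c(NA, NA, NA))
  zmax <- min(shr[3], slab_mm)
  for (i in 1:300) {
    z <- runif(1, -zmax, zmax)
    p <- runif(2, -1, 1) * shr[1:2]
    if (sum((c(p, z) / shr)^2) > 1) next
    if (nrow(placed) > 0) {
      dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - c(p, z))^2))
      if (any(dd < placed[, 4] + gap_plus_r)) next
    }
    return(c(p, z))
  }
  c(NA, NA, NA)
}

#' Synthetic cohort specification
#'
#' A labeled two-class cohort in which the classes differ only in their
#' expected hole count (`lambda_mutant` vs `lambda_wildtype`); everything
#' else — per-case voxel spacing and noise level, drawn uniformly from the
#' declared ranges — is label-independent nuisance variation mimicking
#' scanner diversity.
#'
#' @param n_mutant,n_wildtype Cases per class (>= 2 each).
#' @param lambda_mutant,lambda_wildtype Class-conditional Poisson hole means.
#' @param base A [phantom_spec()] template for the non-varied parameters.
#' @param spacing_xy_range,spacing_z_range,noise_range Nuisance ranges (mm,
#'   mm, HU).
#' @param seed Integer seed; fixes the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mutant = 60, n_wildtype = 60, lambda_mutant = 8,
                        lambda_wildtype = 2, base = phantom_spec(),
                        spacing_xy_range = c(0.6, 0.8),
                        spacing_z_range = c(1.5, 2.5),
                        noise_range = c(10, 20), seed = 1) {
  if (n_mutant < 2 || n_wildtype < 2) stop_param("need >= 2 cases per class")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-case nuisance parameters and seeds from the cohort seed, then
#' generates each case with [generate_case()]. Cohorts with different seeds
#' use disjoint case seed streams.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory: writes per-case NIfTI volume/mask and
#'   a `manifest.csv`.
#' @return A `phantom_cohort`: list with `cases` (list of
#'   volume/mask/meta/case_id/label) and `manifest` (tibble).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  if (!inherits(spec, "cohort_spec")) stop_param("`spec` must be a cohort_spec")
  n <- spec$n_mutant + spec$n_wildtype
  labels <- c(rep("mutant", spec$n_mutant), rep("wildtype", spec$n_wildtype))
  draws <- withr::with_seed(spec$seed, tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    label = labels,
    case_seed = sample.int(.Machine$integer.max - 1L, n),
    sp_xy = runif(n, spec$spacing_xy_range[1], spec$spacing_xy_range[2]),
    sp_z = runif(n, spec$spacing_z_range[1], spec$spacing_z_range[2]),
    noise = runif(n, spec$noise_range[1], spec$noise_range[2]),
    lambda = ifelse(labels == "mutant", spec$lambda_mutant, spec$lambda_wildtype)
  ))
  cases <- purrr::pmap(draws, function(case_id, label, case_seed, sp_xy, sp_z,
                                       noise, lambda) {
    ps <- spec$base
    ps$spacing <- c(sp_xy, sp_xy, sp_z)
    ps$noise_sd_hu <- noise
    ps$hole_lambda <- lambda
    ps$seed <- case_seed
    cs <- generate_case(ps)
    c(list(case_id = case_id, label = label), cs)
  })
  manifest <- dplyr::mutate(draws,
                            n_holes = vapply(cases, function(x) x$meta$n_holes, numeric(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cs in cases) {
      write_nifti_volume(cs$volume, file.path(out_dir, paste0(cs$case_id, "_ct.nii.gz")))
      write_nifti_volume(cs$mask, file.path(out_dir, paste0(cs$case_id, "_mask.nii.gz")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(cases = cases, manifest = manifest, spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$cases), " cases (",
      sum(x$manifest$label == "mutant"), " mutant / ",
      sum(x$manifest$label == "wildtype"), " wildtype), seed ",
      x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Multi-rater mask perturbations
#'
#' Emulates independent re-segmentations: each rater's mask is obtained by
#' adding a smooth zero-mean random field (white noise smoothed with a 3 mm
#' Gaussian, unit variance) scaled by `magnitude` (mm) to the signed
#' distance field of the input mask and re-thresholding at zero — random
#' boundary dilations and erosions of roughly `magnitude` amplitude.
#' Magnitude 0 reproduces the input exactly. A perturbation that would
#' annihilate the mask is retried with the magnitude halved (up to 5
#' times), then raises an error.
#'
#' @param mask A [segmentation_mask()] with foreground.
#' @param magnitude Boundary displacement scale in mm.
#' @param n_raters Number of masks to produce (default 9).
#' @param seed Integer seed.
#' @return List of `n_raters` segmentation masks.
#' @export
perturb_mask <- function(mask, magnitude, n_raters = 9, seed = 1) {
  if (!inherits(mask, "segmentation_mask")) stop_param("need a segmentation_mask")
  if (!any(mask$voxels)) stop_degenerate("mask has no foreground voxels")
  if (magnitude < 0) stop_param("`magnitude` must be >= 0")
  sdf <- signed_distance(mask$voxels, mask$spacing)
  withr::with_seed(seed, {
    lapply(seq_len(n_raters), function(i) {
      if (magnitude == 0)
        return(segmentation_mask(mask$voxels, mask$spacing, mask$origin))
      mag <- magnitude
      for (try in 1:5) {
        field <- smooth_noise_field(dim(mask$voxels), mask$spacing, sigma_mm = 3)
        m <- (sdf + mag * field) < 0
        if (any(m)) return(segmentation_mask(m, mask$spacing, mask$origin))
        mag <- mag / 2
      }
      stop_degenerate("perturbation annihilated the mask")
    })
  })
}

smooth_noise_field <- function(dims, spacing, sigma_mm = 3) {
  f <- array(rnorm(prod(dims)), dims)
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    half <- max(1L, ceiling(3 * sig_vox))
    k <- exp(-((-half:half)^2) / (2 * sig_vox^2))
    C <- conv_matrix(dims[ax], k)
    f <- apply_axis(f, C, ax)
  }
  s <- sd(f)
  if (s == 0) s <- 1
  f / s
}

# Banded convolution matrix with edge-replicated, weight-renormalized rows.
conv_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (kk in seq_along(kernel)) {
    idx <- pmin(pmax(seq_len(n) + (kk - 1L - half), 1L), n)
    C[cbind(seq_len(n), idx)] <- C[cbind(seq_len(n), idx)] + kernel[kk]
  }
  C / rowSums(C)
}

#' Hand-countable Betti fixtures
#'
#' Canonical binary images with known (b0, b1) under the foreground-8 /
#' background-4 convention: full and empty windows, a ring, nested rings, a
#' C shape (its cavity opens to the border, so no hole), a border-touching
#' cavity, two separated blobs, and a diagonal chain (one component under
#' 8-connectivity).
#'
#' @return List of `list(name, image, b0, b1)`.
#' @examples
#' f <- betti_fixtures()
#' f[[3]]$name
#' @export
betti_fixtures <- function() {
  full <- matrix(TRUE, 5, 5)
  empty <- matrix(FALSE, 5, 5)
  ring <- matrix(TRUE, 5, 5)
  ring[2:4, 2:4] <- FALSE
  ring_solidless <- ring # border ring with 3x3 cavity
  nested <- matrix(FALSE, 9, 9)
  nested[1, ] <- nested[9, ] <- nested[, 1] <- nested[, 9] <- TRUE
  nested[4:6, 4:6] <- TRUE
  nested[5, 5] <- FALSE
  blobs <- matrix(FALSE, 7, 7)
  blobs[1:2, 1:2] <- TRUE
  blobs[6:7, 6:7] <- TRUE
  cshape <- matrix(TRUE, 5, 5)
  cshape[2:4, 2:4] <- FALSE
  cshape[3, 5] <- FALSE # open the ring: cavity connects to the border
  cavity <- matrix(TRUE, 5, 5)
  cavity[1:2, 3] <- FALSE # notch from the edge, not enclosed
  diagonal <- matrix(FALSE, 5, 5)
  diag(diagonal) <- TRUE
  list(
    list(name = "full", image = full, b0 = 1L, b1 = 0L),
    list(name = "empty", image = empty, b0 = 0L, b1 = 0L),
    list(name = "ring", image = ring_solidless, b0 = 1L, b1 = 1L),
    list(name = "nested_rings", image = nested, b0 = 2L, b1 = 2L),
    list(name = "two_blobs", image = blobs, b0 = 2L, b1 = 0L),
    list(name = "c_shape", image = cshape, b0 = 1L, b1 = 0L),
    list(name = "border_cavity", image = cavity, b0 = 1L, b1 = 0L),
    list(name = "diagonal_chain", image = diagonal, b0 = 1L, b1 = 0L)
  )
}
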