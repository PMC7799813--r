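#' CT volume and segmentation mask containers
#'
#' Lightweight containers pairing a 3-D voxel array with its physical grid.
#' Axial slices are indexed along the third array axis; indices are 1-based
#' as usual in R. Intensities are Hounsfield units (HU) for CT volumes and
#' logicals for masks.
#'
#' @param voxels 3-D array. HU for volumes; logical/0-1 for masks.
#' @param spacing Numeric length-3, voxel spacing in mm (x, y, z), all > 0.
#' @param origin Numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `ct_volume` or `segmentation_mask`: a list with
#'   elements `voxels`, `spacing`, `origin`.
#' @examples
#' v <- ct_volume(array(-800L, c(8, 8, 4)), spacing = c(0.7, 0.7, 2))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3 || any(dim(voxels) == 0))
    stop_param("`voxels` must be a non-empty 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_param("`spacing` must be three positive numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
segmentation_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3 || any(dim(voxels) == 0))
    stop_param("`voxels` must be a non-empty 3-D array")
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_param("`spacing` must be three positive numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "segmentation_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", min(x$voxels), ", ", max(x$voxels), "]\n", sep = "")
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$voxels), " foreground voxels\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read CT volumes and masks
#'
#' Volumes are read from NIfTI (`.nii`, `.nii.gz`) via RNifti or from plain
#' NRRD (`raw` or `gzip` encoded, attached header). Masks are binarized as
#' `> 0` on read and checked against a reference volume grid when one is
#' supplied.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param reference Optional `ct_volume`; the mask grid must match it.
#' @return [read_ct_volume()] a `ct_volume`; [read_segmentation_mask()] a
#'   `segmentation_mask`.
#' @export
read_ct_volume <- function(path) {
  arr <- read_image_any(path)
  ct_volume(round(arr$data), spacing = arr$spacing, origin = arr$origin)
}

#' @rdname read_ct_volume
#' @export
read_segmentation_mask <- function(path, reference = NULL) {
  arr <- read_image_any(path)
  m <- segmentation_mask(arr$data > 0, spacing = arr$spacing, origin = arr$origin)
  if (!is.null(reference) && !same_grid(m, reference))
    stop_align("mask grid does not match the reference volume grid")
  m
}

read_image_any <- function(path) {
  if (!file.exists(path)) stop_param(paste0("file not found: ", path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  d <- dim(img)
  if (length(d) > 3) {
    img <- array(img, d[1:3])
  } else if (length(d) == 2) {
    img <- array(img, c(d, 1))
    pd <- c(pd[1:2], 1)
  }
  list(data = as.array(img), spacing = as.numeric(pd[1:3]), origin = c(0, 0, 0))
}

#' @rdname read_ct_volume
#' @param volume A `ct_volume` or `segmentation_mask` to write.
#' @export
write_nifti_volume <- function(volume, path) {
  arr <- volume$voxels
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal NRRD reader: attached header, 3-D, encodings raw | gzip, little
# endian. Covers the masks produced by common segmentation tools when saved
# uncompressed or gzip-compressed.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop_param("not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3) stop_param("only 3-D NRRD supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      x <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(x^2))
    }, numeric(1))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  n <- prod(sizes)
  rtype <- switch(tolower(type),
    "signed char" = , "int8" = , "int8_t" = list(what = "integer", size = 1, signed = TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "signed short" = , "int16" = , "int16_t" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "signed int" = , "int32" = , "int32_t" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop_param(paste0("unsupported NRRD type: ", type))
  )
  raw_rest <- readBin(con, "raw", n = file.info(path)$size)
  if (enc %in% c("gzip", "gz")) {
    raw_rest <- memDecompress(raw_rest, type = "gzip")
  } else if (enc != "raw") {
    stop_param(paste0("unsupported NRRD encoding: ", enc))
  }
  vals <- readBin(raw_rest, rtype$what, n = n, size = rtype$size,
                  signed = rtype$signed, endian = "little")
  if (length(vals) < n) stop_param("truncated NRRD data")
  list(data = array(vals, sizes), spacing = spacing, origin = origin)
}
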