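#' Quantitative parametric map
#'
#' A `quant_map` wraps one subject's single-slice 2D relaxation-time map
#' (values in milliseconds) together with its pixel spacing and modality.
#' T1 and T2 maps are inherently quantitative: pixel values are physical
#' tissue properties, which is why downstream discretization uses a fixed
#' bin width in milliseconds rather than a fixed bin count.
#'
#' @param values Numeric matrix of relaxation times (ms); all values finite.
#' @param spacing_mm Pixel spacing in mm; a single number (isotropic) or a
#'   length-2 vector `c(row, col)`.
#' @param modality `"T1"` or `"T2"`.
#' @param subject_id Character identifier.
#' @return An object of class `quant_map`.
#' @export
quant_map <- function(values, spacing_mm, modality = c("T1", "T2"),
                      subject_id = "s01") {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite everywhere", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be one or two positive finite numbers",
         call. = FALSE)
  }
  structure(
    list(values = values, spacing_mm = spacing_mm, modality = modality,
         subject_id = as.character(subject_id)),
    class = "quant_map"
  )
}

#' @export
print.quant_map <- function(x, ...) {
  cat(sprintf("<quant_map> %s %s: %d x %d px @ %.3f x %.3f mm\n",
              x$subject_id, x$modality, nrow(x$values), ncol(x$values),
              x$spacing_mm[1], x$spacing_mm[2]))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A `roi_mask` is a binary 2D mask congruent with a [quant_map()]; foreground
#' pixels mark the myocardium. A minimum of 9 foreground pixels is required so
#' that texture matrices are meaningful.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return An object of class `roi_mask` with a `pixel_count` field.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(m)) stop("`mask` must not contain NA", call. = FALSE)
  n <- sum(m)
  if (n < 9L) {
    stop("ROI must contain at least 9 pixels (got ", n, ")", call. = FALSE)
  }
  structure(list(mask = m, pixel_count = n), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d foreground\n",
              nrow(x$mask), ncol(x$mask), x$pixel_count))
  invisible(x)
}

check_congruent <- function(map, mask) {
  if (!identical(dim(map$values), dim(mask$mask))) {
    stop("map and mask shapes differ (",
         paste(dim(map$values), collapse = "x"), " vs ",
         paste(dim(mask$mask), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

roi_values <- function(map, mask) {
  check_congruent(map, mask)
  map$values[mask$mask]
}

#' Write a subject's map and mask as NIfTI
#'
#' Stores the map and its ROI mask as two NIfTI files
#' (`<stem>_map.nii.gz`, `<stem>_mask.nii.gz`) with the pixel spacing encoded
#' in the header, so a round trip through [read_subject()] reproduces values
#' and spacing exactly.
#'
#' @param map A [quant_map()].
#' @param mask A [roi_mask()] congruent with `map`.
#' @param dir Output directory (created if absent).
#' @param stem File stem; defaults to the subject id.
#' @return Invisibly, a character vector with the two paths written.
#' @export
write_subject <- function(map, mask, dir, stem = map$subject_id) {
  check_congruent(map, mask)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  map_path <- file.path(dir, paste0(stem, "_map.nii.gz"))
  mask_path <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  vals <- map$values
  attr(vals, "pixdim") <- map$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(vals, datatype = "double"), map_path)
  mvals <- matrix(as.integer(mask$mask), nrow(mask$mask))
  attr(mvals, "pixdim") <- map$spacing_mm
  RNifti::writeNifti(RNifti::asNifti(mvals, datatype = "uint8"), mask_path)
  invisible(c(map = map_path, mask = mask_path))
}

#' Read a subject written by [write_subject()]
#'
#' @param dir Directory holding the files.
#' @param stem File stem used at write time.
#' @param modality,subject_id Metadata to attach (NIfTI does not carry them).
#' @return A list with elements `map` ([quant_map()]) and `mask` ([roi_mask()]).
#' @export
read_subject <- function(dir, stem, modality = c("T1", "T2"),
                         subject_id = stem) {
  modality <- match.arg(modality)
  map_path <- file.path(dir, paste0(stem, "_map.nii.gz"))
  mask_path <- file.path(dir, paste0(stem, "_mask.nii.gz"))
  if (!file.exists(map_path) || !file.exists(mask_path)) {
    stop("missing NIfTI files for stem '", stem, "' in ", dir, call. = FALSE)
  }
  img <- RNifti::readNifti(map_path)
  vals <- matrix(as.numeric(img), dim(img)[1], dim(img)[2])
  sp <- RNifti::pixdim(img)[1:2]
  msk <- RNifti::readNifti(mask_path)
  m <- matrix(as.numeric(msk) > 0.5, dim(msk)[1], dim(msk)[2])
  list(map = quant_map(vals, sp, modality, subject_id),
       mask = roi_mask(m))
}
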