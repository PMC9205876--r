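# Cubic B-spline prefilter along columns of `v`, mirror (whole-sample
# symmetric) boundary, exact initialisation. Returns the spline coefficients
# such that the cubic B-spline expansion interpolates the samples.
bspline_coeffs_cols <- function(v) {
  n <- nrow(v)
  if (n == 1L) return(v)
  z <- sqrt(3) - 2
  v <- v * 6
  cp <- v
  # exact causal init for mirror boundary: geometric sum over the period-
  # (2n-2) mirror extension of each line
  if (n > 2L) {
    ext <- rbind(v, v[(n - 1):2, , drop = FALSE])  # length 2n-2
    pw <- z^(0:(2 * n - 3))
    cp[1L, ] <- colSums(ext * pw) / (1 - z^(2 * n - 2))
  } else {
    cp[1L, ] <- (v[1L, ] + z * v[2L, ]) / (1 - z^2)
  }
  for (i in 2:n) cp[i, ] <- v[i, ] + z * cp[i - 1L, ]
  cm <- cp
  cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1L, ])
  for (i in (n - 1L):1L) cm[i, ] <- z * (cm[i + 1L, ] - cp[i, ])
  cm
}

bspline_coeffs_2d <- function(img) {
  t(bspline_coeffs_cols(t(bspline_coeffs_cols(img))))
}

# mirror (reflect about end samples) index, 1-based, period 2n-2
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# cubic B-spline weights for fractional positions t in [0,1); 4 columns for
# support points floor(x)-1 .. floor(x)+2
cubic_weights <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Evaluate the 2D cubic B-spline interpolant of `img` at continuous index
# coordinates (0-based) given by grids `ri` (rows) and `ci` (cols).
bspline_eval_grid <- function(img, ri, ci) {
  cf <- bspline_coeffs_2d(img)
  n <- nrow(img); m <- ncol(img)
  fr <- floor(ri); fc <- floor(ci)
  wr <- cubic_weights(ri - fr)
  wc <- cubic_weights(ci - fc)
  idx_r <- vapply(0:3, function(a) mirror_index(fr - 1 + a + 1, n),
                  integer(length(ri)))
  idx_c <- vapply(0:3, function(b) mirror_index(fc - 1 + b + 1, m),
                  integer(length(ci)))
  out <- matrix(0, length(ri), length(ci))
  for (a in 1:4) {
    for (b in 1:4) {
      out <- out + outer(wr[, a], wc[, b]) *
        cf[idx_r[, a], idx_c[, b], drop = FALSE]
    }
  }
  out
}

#' Resample a map and its ROI to an isotropic target spacing
#'
#' The map is interpolated with a cubic B-spline (order 3, mirror boundary,
#' exact prefilter) on an output grid whose origin coincides with the input
#' origin; the mask is resampled by nearest neighbour and re-binarized.
#' The output grid covers the physical extent of the input without
#' extrapolation.
#'
#' @param map A [quant_map()].
#' @param mask A [roi_mask()] congruent with `map`.
#' @param target_spacing_mm Target isotropic spacing, in `[1, 5]` mm.
#' @return A list with resampled `map` and `mask`.
#' @export
resample_map <- function(map, mask, target_spacing_mm) {
  check_congruent(map, mask)
  if (!is.numeric(target_spacing_mm) || length(target_spacing_mm) != 1L ||
      target_spacing_mm < 1 || target_spacing_mm > 5) {
    stop("`target_spacing_mm` must be a single value in [1, 5]",
         call. = FALSE)
  }
  sp <- map$spacing_mm
  n <- nrow(map$values); m <- ncol(map$values)
  n_out <- floor((n - 1) * sp[1] / target_spacing_mm) + 1
  m_out <- floor((m - 1) * sp[2] / target_spacing_mm) + 1
  ri <- (seq_len(n_out) - 1) * target_spacing_mm / sp[1]
  ci <- (seq_len(m_out) - 1) * target_spacing_mm / sp[2]
  vals <- bspline_eval_grid(map$values, ri, ci)
  # nearest-neighbour mask resampling, then re-binarize
  nn_r <- pmin(pmax(round(ri) + 1, 1), n)
  nn_c <- pmin(pmax(round(ci) + 1, 1), m)
  msk <- mask$mask[nn_r, nn_c, drop = FALSE]
  if (sum(msk) < 9L) {
    stop("resampling left a degenerate ROI (", sum(msk), " pixels)",
         call. = FALSE)
  }
  list(
    map = quant_map(vals, target_spacing_mm, map$modality, map$subject_id),
    mask = roi_mask(msk)
  )
}
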