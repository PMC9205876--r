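#' Spatial filter names
#'
#' The closed set of filter tokens accepted by [apply_filter()] and the
#' pipeline configuration: the unfiltered map, the four single-level
#' undecimated Daubechies-3 wavelet sub-bands, the spacing-aware gradient
#' magnitude, and the per-pixel square and square-root maps.
#'
#' @return Character vector of the eight filter names.
#' @export
filter_names <- function() {
  c("original", "wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
    "gradient", "square", "square-root")
}

# Daubechies-3 orthonormal scaling filter (sum = sqrt(2), norm 1); the
# tabulated values are renormalised so the low-pass sum is exactly sqrt(2)
DB3_H <- local({
  h <- c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
         -0.13501102001039084, -0.08544127388224149, 0.035226291882100656)
  h * sqrt(2) / sum(h)
})
# quadrature mirror high-pass: g[k] = (-1)^k h[N-1-k]; mean removed so a
# constant signal is annihilated exactly
DB3_G <- local({
  g <- rev(DB3_H) * c(1, -1, 1, -1, 1, -1)
  g - mean(g)
})

# periodic convolution along rows of `x` (i.e., filtering each column):
# y[i,] = sum_k f[k+1] * x[(i - k) mod n, ]
pconv_rows <- function(x, f) {
  n <- nrow(x)
  y <- matrix(0, n, ncol(x))
  for (k in seq_along(f) - 1L) {
    idx <- ((seq_len(n) - 1L - k) %% n) + 1L
    y <- y + f[k + 1L] * x[idx, , drop = FALSE]
  }
  y
}

# adjoint (correlation): y[i,] = sum_k f[k+1] * x[(i + k) mod n, ]
pcorr_rows <- function(x, f) {
  n <- nrow(x)
  y <- matrix(0, n, ncol(x))
  for (k in seq_along(f) - 1L) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    y <- y + f[k + 1L] * x[idx, , drop = FALSE]
  }
  y
}

#' Single-level undecimated Daubechies-3 wavelet decomposition
#'
#' Stationary (a trous) 2D wavelet transform with periodic boundary
#' extension, so each sub-band is congruent with the input grid as required
#' for ROI-based feature extraction. Analysis filters are normalised by
#' 1/sqrt(2) per axis, which keeps the LL band of a constant map at the
#' original intensity (convenient when filtered maps are discretized with
#' the same fixed bin width) and makes [swt2_reconstruct()] an exact inverse.
#'
#' @param x Numeric matrix.
#' @return List with matrices `LL`, `LH`, `HL`, `HH`. The first letter is the
#'   filter applied along the horizontal (column) axis, the second along the
#'   vertical (row) axis.
#' @export
swt2_db3 <- function(x) {
  h <- DB3_H / sqrt(2); g <- DB3_G / sqrt(2)
  lo_r <- pconv_rows(x, h); hi_r <- pconv_rows(x, g)
  lo_rc <- function(m, f) t(pconv_rows(t(m), f))
  list(
    LL = lo_rc(lo_r, h), LH = lo_rc(hi_r, h),
    HL = lo_rc(lo_r, g), HH = lo_rc(hi_r, g)
  )
}

#' Reconstruct a map from its four undecimated sub-bands
#'
#' Exact inverse of [swt2_db3()] (synthesis by the adjoint filters); used to
#' verify perfect reconstruction.
#'
#' @param bands List as returned by [swt2_db3()].
#' @return Numeric matrix.
#' @export
swt2_reconstruct <- function(bands) {
  h <- DB3_H / sqrt(2); g <- DB3_G / sqrt(2)
  col_corr <- function(m, f) t(pcorr_rows(t(m), f))
  pcorr_rows(col_corr(bands$LL, h), h) +
    pcorr_rows(col_corr(bands$LH, h), g) +
    pcorr_rows(col_corr(bands$HL, g), h) +
    pcorr_rows(col_corr(bands$HH, g), g)
}

# spacing-aware gradient magnitude: central differences in the interior,
# one-sided at the edges
gradient_magnitude <- function(v, spacing) {
  n <- nrow(v); m <- ncol(v)
  gr <- v; gc <- v
  if (n >= 3) {
    gr[2:(n - 1), ] <- (v[3:n, ] - v[1:(n - 2), ]) / (2 * spacing[1])
  }
  gr[1, ] <- (v[2, ] - v[1, ]) / spacing[1]
  gr[n, ] <- (v[n, ] - v[n - 1, ]) / spacing[1]
  if (m >= 3) {
    gc[, 2:(m - 1)] <- (v[, 3:m] - v[, 1:(m - 2)]) / (2 * spacing[2])
  }
  gc[, 1] <- (v[, 2] - v[, 1]) / spacing[2]
  gc[, m] <- (v[, m] - v[, m - 1]) / spacing[2]
  sqrt(gr^2 + gc^2)
}

#' Apply a spatial filter to a map
#'
#' `original` is the identity; `square` is per-pixel x^2; `square-root` is
#' per-pixel sqrt(|x|); `gradient` is the Euclidean magnitude of the
#' spacing-aware 2D central-difference gradient (ms/mm); the `wavelet-XY`
#' names select the corresponding sub-band of [swt2_db3()]. The output grid
#' is congruent with the input.
#'
#' @param map A [quant_map()].
#' @param filter One of [filter_names()].
#' @return A [quant_map()] with filtered values.
#' @export
apply_filter <- function(map, filter) {
  if (!is.character(filter) || length(filter) != 1L ||
      !(filter %in% filter_names())) {
    stop("unknown filter name: ", paste(filter, collapse = ", "),
         "; valid names: ", paste(filter_names(), collapse = ", "),
         call. = FALSE)
  }
  v <- map$values
  out <- switch(
    filter,
    "original" = v,
    "square" = v^2,
    "square-root" = sqrt(abs(v)),
    "gradient" = gradient_magnitude(v, map$spacing_mm),
    {
      band <- sub("wavelet-", "", filter)
      swt2_db3(v)[[band]]
    }
  )
  quant_map(out, map$spacing_mm, map$modality, map$subject_id)
}
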