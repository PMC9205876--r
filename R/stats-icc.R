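# Intraclass correlation for preprocessing robustness: two-way mixed
# effects model, single rater, absolute agreement. Each preprocessing
# condition (voxel size, bin width or filter) plays the role of a rater.

#' Two-way crossed ANOVA mean squares
#'
#' Standard decomposition of an n x k complete matrix (subjects x raters)
#' into between-subject (rows), between-measurement (columns) and error
#' mean squares, with degrees of freedom n - 1, k - 1 and (n - 1)(k - 1).
#'
#' @param data Numeric n x k matrix, no missing cells.
#' @return A list with `MS_R`, `MS_C`, `MS_E`, `n`, `k`.
#' @export
anova_components <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("`data` must have no missing cells", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("need n >= 2 subjects and k >= 2 raters",
                           call. = FALSE)
  g <- mean(data)
  rm_ <- rowMeans(data); cm_ <- colMeans(data)
  ss_r <- k * sum((rm_ - g)^2)
  ss_c <- n * sum((cm_ - g)^2)
  resid <- data - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g
  ss_e <- sum(resid^2)
  list(MS_R = ss_r / (n - 1), MS_C = ss_c / (k - 1),
       MS_E = ss_e / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Stratify an ICC value into variability bands
#'
#' Half-open bands: high variability (ICC <= 0.5), considerable
#' (0.5 < ICC <= 0.75), moderate (0.75 < ICC <= 0.9), low
#' (0.9 < ICC <= 1). Boundary values fall in the lower band.
#'
#' @param value ICC value (<= 1; negative values allowed).
#' @return Character scalar (or vector) of band labels.
#' @export
stratify_icc <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v <= 0.5) "high" else if (v <= 0.75) "considerable"
    else if (v <= 0.9) "moderate" else "low"
  }, character(1))
}

#' Intraclass correlation coefficient (two-way mixed, absolute agreement)
#'
#' Computes
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E + (k / n)(MS_C - MS_E))`
#' from the two-way crossed mean squares: the single-rater absolute-
#' agreement form. Values at or below 0 indicate that the preprocessing
#' variability swamps the between-subject variance; they are reported as
#' computed and banded as high variability. A matrix whose cells are all
#' identical makes the ratio 0/0; that degenerate case is defined as
#' ICC = 1 and flagged.
#'
#' @param data Numeric n x k matrix (subjects x conditions).
#' @return An object of class `icc_estimate`: list with `value`, `band`,
#'   `components`, `degenerate`.
#' @export
icc <- function(data) {
  comp <- anova_components(data)
  num <- comp$MS_R - comp$MS_E
  den <- comp$MS_R + (comp$k - 1) * comp$MS_E +
    (comp$k / comp$n) * (comp$MS_C - comp$MS_E)
  degenerate <- den == 0
  value <- if (degenerate) 1 else num / den
  structure(
    list(value = value, band = stratify_icc(value), components = comp,
         degenerate = degenerate),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%s variability%s)\n", x$value, x$band,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icc_estimate <- function(x, ...) {
  tibble::tibble(
    icc = x$value, band = x$band, degenerate = x$degenerate,
    MS_R = x$components$MS_R, MS_C = x$components$MS_C,
    MS_E = x$components$MS_E, n = x$components$n, k = x$components$k
  )
}
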