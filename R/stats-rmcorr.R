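# Repeated-measures correlation: the common within-subject linear
# association between a preprocessing parameter and a feature estimate,
# obtained from an ANCOVA with subject as a factor and a common slope.

#' Repeated-measures correlation
#'
#' Fits `y ~ subject + x` (subject as a factor, common slope for `x`) and
#' returns the repeated-measures correlation
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, where `SS_x` is
#' the sequential sum of squares for `x` after adjusting for subjects. For
#' a balanced design with N subjects and k measurements each, the error
#' degrees of freedom are `N(k - 1) - 1`; unbalanced designs use the
#' residual df of the fit. The p-value comes from the t distribution with
#' those df.
#'
#' @param data A data frame.
#' @param subject,x,y Column names (strings) of the subject identifier, the
#'   varied preprocessing value and the feature value.
#' @return An object of class `rmcorr_fit` with fields `r_rm`, `df`,
#'   `p_value`, `slope`, `n_subjects`, `n_obs`.
#' @export
rmcorr <- function(data, subject = "subject_id", x = "x", y = "y") {
  df_ <- data.frame(
    subject = factor(data[[subject]]),
    x = as.numeric(data[[x]]),
    y = as.numeric(data[[y]])
  )
  df_ <- df_[stats::complete.cases(df_), ]
  if (nlevels(droplevels(df_$subject)) < 2L) {
    stop("rmcorr needs at least 2 subjects", call. = FALSE)
  }
  df_$subject <- droplevels(df_$subject)
  if (any(tapply(df_$x, df_$subject, function(v) length(v) < 2L))) {
    stop("each subject needs at least 2 observations", call. = FALSE)
  }
  within_var <- tapply(df_$x, df_$subject, stats::var)
  if (all(within_var == 0)) {
    stop("zero within-subject variance in `x`", call. = FALSE)
  }
  fit <- stats::lm(y ~ subject + x, data = df_)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits are legitimate here
  ss_x <- an["x", "Sum Sq"]
  ss_e <- an["Residuals", "Sum Sq"]
  dfe <- an["Residuals", "Df"]
  slope <- stats::coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  tstat <- r * sqrt(dfe / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), dfe)
  structure(
    list(r_rm = r, df = dfe, p_value = p, slope = slope,
         n_subjects = nlevels(df_$subject), n_obs = nrow(df_)),
    class = "rmcorr_fit"
  )
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.4f, df = %d, p = %.3g\n",
              x$r_rm, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.rmcorr_fit <- function(x, ...) {
  tibble::tibble(estimate = x$r_rm, df = x$df, p.value = x$p_value,
                 slope = x$slope)
}

#' @export
glance.rmcorr_fit <- function(x, ...) {
  tibble::tibble(r_rm = x$r_rm, df = x$df, p.value = x$p_value,
                 n_subjects = x$n_subjects, n_obs = x$n_obs)
}

#' Bonferroni adjustment within one test family
#'
#' Flags a test as significant iff `p <= alpha / m`, where `m` is the family
#' size (by default the number of p-values supplied: all features tested for
#' one modality x effect x varied element).
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Family size; defaults to `length(p_values)`.
#' @return A tibble with `p_value`, `p_bonferroni` (capped at 1) and
#'   `significant`.
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    p_value = p_values,
    p_bonferroni = pmin(1, p_values * m),
    significant = !is.na(p_values) & p_values <= alpha / m
  )
}
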