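# Coefficient-of-variation analysis: absolute (scale-relative) variability
# of one feature across the varied preprocessing conditions, at otherwise
# fixed settings, per subject.

#' Coefficient of variation (percent)
#'
#' `100 * SD / |mean|` with the sample (n - 1) standard deviation; returns
#' `NA` (flagged undefined) when the mean is zero.
#'
#' @param values Numeric vector of feature estimates across the varied
#'   conditions (length >= 2, no NA).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) {
    stop("need at least 2 values for a CV", call. = FALSE)
  }
  if (anyNA(values)) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / abs(m)
}

#' Median CV across subjects and fixed conditions
#'
#' Summarises a set of per-subject CV records for one feature and one
#' effect; undefined CVs are dropped first. This mirrors the study layout:
#' varying voxel size yields one CV per subject and fixed bin width
#' (n_subjects x 9 records), varying bin width one per subject and fixed
#' voxel size (n_subjects x 7), varying filter one per subject.
#'
#' @param cv_values Numeric vector of CV records (percent), possibly with
#'   NA for undefined entries.
#' @return Median CV (percent), or `NA` if every record is undefined.
#' @export
cv_summary <- function(cv_values) {
  ok <- cv_values[!is.na(cv_values)]
  if (length(ok) == 0L) return(NA_real_)
  stats::median(ok)
}
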