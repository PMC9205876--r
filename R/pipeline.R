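# End-to-end orchestration of the three preprocessing sensitivity designs:
#   A - vary resampling voxel size (per fixed bin width)
#   B - vary bin width (per fixed voxel size)
#   C - vary spatial filter at fixed voxel size and bin width
# A and B are two slicings of the same voxel-size x bin-width feature grid,
# which is extracted once per subject and reused.

#' Default effect designs for a modality
#'
#' Effects A and B share a 7 x 9 grid: voxel sizes 1.8-2.4 mm in 0.1 mm
#' steps, bin widths 3.60-6.40 ms in 0.35 ms steps (T1) or 0.49-0.57 ms in
#' 0.01 ms steps (T2), all chosen so that the quantization level count for
#' a typical ROI range stays within 30-130. Effect C fixes 2.1 mm and
#' 6 ms (T1) / 0.56 ms (T2) and varies the seven spatial filters (the
#' unfiltered map is not one of the raters unless
#' `include_original = TRUE`).
#'
#' @param modality `"T1"` or `"T2"`.
#' @param include_original Include the unfiltered map as an eighth rater in
#'   effect C (default `FALSE`).
#' @return A named list of three `effect_design` objects (`A`, `B`, `C`).
#' @export
default_designs <- function(modality = c("T1", "T2"),
                            include_original = FALSE) {
  modality <- match.arg(modality)
  voxels <- seq(1.8, 2.4, by = 0.1)
  bins <- if (modality == "T1") {
    seq(3.60, 6.40, by = 0.35)
  } else {
    seq(0.49, 0.57, by = 0.01)
  }
  fixed_bin <- if (modality == "T1") 6 else 0.56
  filters <- setdiff(filter_names(), if (include_original) NULL else "original")
  design <- function(id, vox, bw, flt = "original", fixed = list()) {
    structure(list(effect_id = id, modality = modality,
                   voxel_sizes_mm = vox, bin_widths_ms = bw,
                   filters = flt, fixed = fixed),
              class = "effect_design")
  }
  list(
    A = design("A", voxels, bins),
    B = design("B", voxels, bins),
    C = design("C", 2.1, fixed_bin, filters,
               fixed = list(voxel_size_mm = 2.1, bin_width_ms = fixed_bin))
  )
}

#' @export
print.effect_design <- function(x, ...) {
  cat(sprintf("<effect_design %s> %s: %d voxel sizes x %d bin widths x %d filters\n",
              x$effect_id, x$modality, length(x$voxel_sizes_mm),
              length(x$bin_widths_ms), length(x$filters)))
  invisible(x)
}

#' Extract the feature table for one effect design over a cohort
#'
#' Runs the per-coordinate pipeline (resample, filter, discretize, extract)
#' over every subject and coordinate of the design. For effects A/B this is
#' the shared voxel-size x bin-width grid with 98 features per coordinate;
#' for effect C it is the filter set at the fixed coordinate with 89
#' features per filter. Subject-coordinate combinations whose ROI
#' degenerates under resampling are skipped and recorded in the
#' `"dropped"` attribute.
#'
#' @param cohort A [generate_cohort()] result (or any tibble with `map` and
#'   `mask` list-columns).
#' @param design An `effect_design` from [default_designs()].
#' @return A long tibble: `subject_id`, `modality`, `effect`,
#'   `voxel_size_mm`, `bin_width_ms`, `filter`, `feature_class`,
#'   `feature_name`, `value`.
#' @export
run_effect <- function(cohort, design) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  out <- list()
  dropped <- list()
  for (s in seq_len(nrow(cohort))) {
    map <- cohort$map[[s]]; mask <- cohort$mask[[s]]
    for (vox in design$voxel_sizes_mm) {
      rs <- tryCatch(resample_map(map, mask, vox), error = function(e) e)
      if (inherits(rs, "error")) {
        dropped[[length(dropped) + 1L]] <- list(
          subject_id = map$subject_id, voxel_size_mm = vox,
          reason = conditionMessage(rs))
        next
      }
      for (flt in design$filters) {
        for (bw in design$bin_widths_ms) {
          feats <- extract_features(rs$map, rs$mask, bw, flt)
          out[[length(out) + 1L]] <- tibble::tibble(
            subject_id = map$subject_id, modality = map$modality,
            effect = design$effect_id, voxel_size_mm = vox,
            bin_width_ms = bw, filter = flt, feats)
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "dropped") <- dplyr::bind_rows(dropped)
  res
}

listwise_matrix <- function(df, row_col, col_col) {
  wide <- tidyr::pivot_wider(df, id_cols = dplyr::all_of(row_col),
                             names_from = dplyr::all_of(col_col),
                             values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[row_col]]
  m[stats::complete.cases(m), , drop = FALSE]
}

#' ICC, CV and rmcorr tables for one effect
#'
#' For effect A, one ICC per feature and fixed bin width over the
#' subjects x voxel-sizes matrix, and one CV per subject and fixed bin
#' width over the voxel sizes; effect B is symmetric with bin widths
#' varied; effect C has a single fixed coordinate with filters as raters.
#' Undefined feature values are removed listwise per ICC matrix (dropped
#' subject counts are reported). Repeated-measures correlation against the
#' varied parameter is computed for effects A and B only, at a single fixed
#' value of the complementary parameter (default: its grid median), with
#' Bonferroni correction over the features of the family.
#'
#' @param features A [run_effect()] table.
#' @param design The matching `effect_design`.
#' @param rmcorr_fixed Fixed complementary value at which the rmcorr runs;
#'   `NULL` picks the median grid value.
#' @return A list of class `effect_analysis` with tibbles `icc`, `cv`,
#'   `cv_summary` and (effects A/B) `rmcorr`.
#' @export
analyze_effect <- function(features, design, rmcorr_fixed = NULL) {
  eff <- design$effect_id
  if (eff == "A") {
    varied <- "voxel_size_mm"; fixed <- "bin_width_ms"
  } else if (eff == "B") {
    varied <- "bin_width_ms"; fixed <- "voxel_size_mm"
  } else {
    varied <- "filter"; fixed <- NULL
  }

  grp <- c("feature_class", "feature_name", fixed)
  icc_tbl <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      m <- listwise_matrix(df[, c("subject_id", varied, "value")],
                           "subject_id", varied)
      n_drop <- length(unique(df$subject_id)) - nrow(m)
      if (nrow(m) < 2L || ncol(m) < 2L) {
        return(tibble::tibble(icc = NA_real_, band = NA_character_,
                              degenerate = NA, n = nrow(m), k = ncol(m),
                              n_dropped = n_drop))
      }
      est <- icc(m)
      tibble::tibble(icc = est$value, band = est$band,
                     degenerate = est$degenerate,
                     n = est$components$n, k = est$components$k,
                     n_dropped = n_drop)
    }) |>
    dplyr::ungroup()

  cv_tbl <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("subject_id", "feature_class", "feature_name", fixed)))) |>
    dplyr::summarise(
      cv_percent = if (any(is.na(.data$value))) NA_real_
                   else cv_percent(.data$value),
      .groups = "drop")

  cvs_tbl <- cv_tbl |>
    dplyr::group_by(.data$feature_class, .data$feature_name) |>
    dplyr::summarise(median_cv = cv_summary(.data$cv_percent),
                     n_records = sum(!is.na(.data$cv_percent)),
                     .groups = "drop")

  out <- list(effect = eff, icc = icc_tbl, cv = cv_tbl, cv_summary = cvs_tbl)

  if (eff %in% c("A", "B")) {
    fixed_vals <- sort(unique(features[[fixed]]))
    if (is.null(rmcorr_fixed)) {
      rmcorr_fixed <- fixed_vals[ceiling(length(fixed_vals) / 2)]
    }
    sub <- features[features[[fixed]] == rmcorr_fixed, ]
    rm_tbl <- sub |>
      dplyr::group_by(.data$feature_class, .data$feature_name) |>
      dplyr::group_modify(function(df, key) {
        df <- df[!is.na(df$value), ]
        fit <- tryCatch(rmcorr(df, "subject_id", varied, "value"),
                        error = function(e) NULL)
        if (is.null(fit)) {
          return(tibble::tibble(r_rm = NA_real_, df = NA_integer_,
                                p_value = NA_real_))
        }
        tibble::tibble(r_rm = fit$r_rm, df = fit$df, p_value = fit$p_value)
      }) |>
      dplyr::ungroup()
    adj <- bonferroni(rm_tbl$p_value, m = sum(!is.na(rm_tbl$p_value)))
    rm_tbl$p_bonferroni <- adj$p_bonferroni
    rm_tbl$significant <- adj$significant
    rm_tbl$fixed_value <- rmcorr_fixed
    out$rmcorr <- rm_tbl
  }
  structure(out, class = "effect_analysis")
}

#' @export
print.effect_analysis <- function(x, ...) {
  cat(sprintf("<effect_analysis %s> %d ICC rows, %d CV records\n",
              x$effect, nrow(x$icc), nrow(x$cv)))
  invisible(x)
}

#' Run the full study pipeline for one modality
#'
#' Generates (or accepts) a cohort, extracts the shared voxel x bin grid
#' once, slices it into effects A and B, runs effect C at its fixed
#' coordinate, and analyses all three. A run manifest (seed, grid sizes,
#' record counts, dropped records) is attached as attribute `"manifest"`.
#'
#' @param spec A [cohort_spec()]; ignored if `cohort` is supplied.
#' @param cohort Optional pre-generated cohort.
#' @param designs Optional list from [default_designs()].
#' @return A list with `cohort`, `features` (named by effect), `analysis`
#'   (named by effect).
#' @export
run_study <- function(spec = cohort_spec(), cohort = NULL, designs = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(spec)
  modality <- cohort$map[[1]]$modality
  if (is.null(designs)) designs <- default_designs(modality)
  grid_feats <- run_effect(cohort, designs$A)   # shared 7 x 9 grid
  feats_a <- grid_feats
  feats_b <- dplyr::mutate(grid_feats, effect = "B")
  feats_c <- run_effect(cohort, designs$C)
  analysis <- list(
    A = analyze_effect(feats_a, designs$A),
    B = analyze_effect(feats_b, designs$B),
    C = analyze_effect(feats_c, designs$C)
  )
  res <- list(cohort = cohort,
              features = list(A = feats_a, B = feats_b, C = feats_c),
              analysis = analysis)
  attr(res, "manifest") <- list(
    seed = attr(cohort, "manifest")$seed,
    modality = modality,
    n_subjects = nrow(cohort),
    grid = list(voxel_sizes = designs$A$voxel_sizes_mm,
                bin_widths = designs$A$bin_widths_ms,
                filters = designs$C$filters),
    n_feature_rows = vapply(res$features, nrow, integer(1)),
    n_dropped = vapply(res$features,
                       function(f) nrow(attr(f, "dropped") %||%
                                          tibble::tibble()),
                       integer(1))
  )
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
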