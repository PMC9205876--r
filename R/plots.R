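# ggplot2 visualisations mirroring the standard presentation of
# preprocessing-robustness results: ICC band heatmaps (feature x fixed
# condition) and CV distributions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of ICC bands for one effect analysis
#'
#' One tile per feature and fixed condition, coloured by variability band
#' (high / considerable / moderate / low), the layout used to summarise
#' ICC results per feature class.
#'
#' @param object An `effect_analysis` from [analyze_effect()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_analysis <- function(object, ...) {
  icc_tbl <- object$icc
  fixed_col <- setdiff(names(icc_tbl),
                       c("feature_class", "feature_name", "icc", "band",
                         "degenerate", "n", "k", "n_dropped"))
  if (length(fixed_col) == 0L) {
    icc_tbl$fixed <- "fixed"
  } else {
    icc_tbl$fixed <- factor(icc_tbl[[fixed_col[1]]])
  }
  icc_tbl$band <- factor(icc_tbl$band,
                         levels = c("high", "considerable", "moderate",
                                    "low"))
  ggplot2::ggplot(icc_tbl,
                  ggplot2::aes(x = .data$fixed, y = .data$feature_name,
                               fill = .data$band)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$feature_class),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(high = "#d73027", considerable = "#fc8d59",
                 moderate = "#fee08b", low = "#1a9850"),
      drop = FALSE, na.value = "grey60") +
    ggplot2::labs(x = "fixed condition", y = NULL, fill = "variability",
                  title = sprintf("ICC bands, effect %s", object$effect)) +
    ggplot2::theme_minimal(base_size = 8)
}

#' Boxplot of per-subject CV values per feature
#'
#' @param analysis An `effect_analysis`.
#' @param feature_classes Optional subset of classes to show.
#' @return A ggplot object.
#' @export
plot_cv_distribution <- function(analysis,
                                 feature_classes = NULL) {
  cv_tbl <- analysis$cv
  if (!is.null(feature_classes)) {
    cv_tbl <- cv_tbl[cv_tbl$feature_class %in% feature_classes, ]
  }
  ggplot2::ggplot(cv_tbl,
                  ggplot2::aes(x = .data$feature_name,
                               y = .data$cv_percent)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_class),
                        scales = "free") +
    ggplot2::labs(x = NULL, y = "CV (%)",
                  title = sprintf("Per-subject CV, effect %s",
                                  analysis$effect)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Display a quantitative map with its ROI outline
#'
#' @param object A [quant_map()].
#' @param mask Optional [roi_mask()] drawn as an overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quant_map <- function(object, mask = NULL, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object$values)),
    col = as.vector(col(object$values)),
    value = as.vector(object$values)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = sprintf("%s (ms)",
                                                 object$modality)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$subject_id, x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mdf <- tibble::tibble(
      row = as.vector(row(mask$mask))[as.vector(mask$mask)],
      col = as.vector(col(mask$mask))[as.vector(mask$mask)]
    )
    p <- p + ggplot2::geom_tile(data = mdf,
                                ggplot2::aes(x = .data$col, y = .data$row),
                                fill = NA, colour = "white",
                                linewidth = 0.05, inherit.aes = FALSE)
  }
  p
}
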