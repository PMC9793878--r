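#' Scatter plot of a variance decomposition
#'
#' Disease-explained variance against confounder-explained variance, one
#' point per feature, significant features (two-way ANOVA disease p < alpha)
#' highlighted. The identity line separates features where disease explains
#' more than the confounder from those dominated by it.
#'
#' @param vd a tibble from [decompose_all()]
#' @return a ggplot object
#' @export
plot_variance_decomposition <- function(vd) {
  vd <- dplyr::filter(vd, !.data$degenerate)
  ggplot2::ggplot(vd, ggplot2::aes(
    x = .data$eta2_confounder, y = .data$eta2_disease,
    colour = .data$significant
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#2166ac")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = paste0("variance explained by ", unique(vd$confounder)[1]),
      y = "variance explained by disease status",
      colour = "disease p < 0.05"
    ) +
    ggplot2::theme_minimal()
}

#' Ordination scatter plot
#'
#' @param object a `crossbiome_ordination`
#' @param meta optional metadata tibble; when given, points are coloured by
#'   `colour_by`
#' @param colour_by metadata column for the colour aesthetic
#' @param ... unused
#' @return a ggplot object
#' @method autoplot crossbiome_ordination
#' @export
autoplot.crossbiome_ordination <- function(object, meta = NULL,
                                           colour_by = "group", ...) {
  co <- object$coordinates
  pe <- round(100 * object$proportion_explained, 1)
  p <- if (!is.null(meta)) {
    co$colour <- meta[[colour_by]][match(co$sample_id, meta$sample_id)]
    ggplot2::ggplot(co, ggplot2::aes(
      x = .data$Axis1, y = .data$Axis2,
      colour = .data$colour
    )) +
      ggplot2::labs(colour = colour_by)
  } else {
    ggplot2::ggplot(co, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  }
  p +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = paste0("PCo1 (", pe[1], "%)"),
      y = paste0("PCo2 (", ifelse(length(pe) >= 2, pe[2], NA), "%)")
    ) +
    ggplot2::theme_minimal()
}

#' Stacked composition bars
#'
#' @param cs a tibble from [composition_summary()]
#' @param top_n collapse all but the `top_n` most abundant taxa into "other"
#' @return a ggplot object
#' @export
plot_composition <- function(cs, top_n = 10) {
  keep <- cs |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(m = mean(.data$mean_rel_abundance)) |>
    dplyr::slice_max(.data$m, n = top_n) |>
    dplyr::pull(.data$taxon)
  cs <- cs |>
    dplyr::mutate(taxon = ifelse(.data$taxon %in% keep, .data$taxon, "other")) |>
    dplyr::group_by(.data$group, .data$taxon) |>
    dplyr::summarise(mean_rel_abundance = sum(.data$mean_rel_abundance), .groups = "drop")
  ggplot2::ggplot(cs, ggplot2::aes(
    x = .data$group, y = .data$mean_rel_abundance,
    fill = .data$taxon
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean relative abundance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Differential-abundance count bars
#'
#' Number of significantly enriched / depleted genera per comparison — the
#' usual overview bar chart of a multi-strategy differential analysis.
#'
#' @param results a tibble from [run_comparison()] (several comparisons may
#'   be row-bound)
#' @return a ggplot object
#' @export
plot_differential_counts <- function(results) {
  counts <- results |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$comparison, .data$direction)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$comparison, y = .data$n,
    fill = .data$direction
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "significant genera", fill = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of a random-forest result
#'
#' @param object an `rf_result`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot rf_result
#' @export
autoplot.rf_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Importance bars of a random-forest result
#'
#' @param res an `rf_result`
#' @param top_n number of features shown
#' @return a ggplot object
#' @export
plot_importance <- function(res, top_n = 30) {
  imp <- res$importance |> dplyr::slice_head(n = top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$mean_decrease_accuracy,
    y = stats::reorder(.data$feature, .data$mean_decrease_accuracy)
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a transfer matrix
#'
#' @param object a `transfer_matrix`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot transfer_matrix
#' @export
autoplot.transfer_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$test, y = .data$train,
    fill = .data$auc
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc)),
      size = 3, na.rm = TRUE
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac",
      midpoint = 0.5, limits = c(0, 1), na.value = "grey90"
    ) +
    ggplot2::labs(x = "test cohort", y = "training cohort", fill = "AUC") +
    ggplot2::theme_minimal()
}
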