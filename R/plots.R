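#' Plot averaged feature importances
#'
#' Horizontal bar chart of the mean gain importance across the five
#' base learners.
#'
#' @param object A `sens_importance` from [average_importance()].
#' @param top_n Number of features shown; default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_importance
#' @export
autoplot.sens_importance <- function(object, top_n = 15, ...) {
  tab <- utils::head(object[order(-object$mean_gain), ], top_n)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$mean_gain,
    y = stats::reorder(.data$feature, .data$mean_gain)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean gain importance (5 learners)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Summary plot of averaged SHAP attributions
#'
#' Beeswarm-style summary: one jittered point per substance per
#' feature, positioned by the averaged attribution (margin scale) and
#' colored by the feature's value scaled to [0, 1]. Features are
#' ordered by mean absolute attribution.
#'
#' @param object A `sens_shap` from [shap_attributions()].
#' @param top_n Number of features shown; default 10.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_shap
#' @export
autoplot.sens_shap <- function(object, top_n = 10, ...) {
  ranking <- shap_summary_ranking(object)
  feats <- utils::head(ranking$feature, top_n)
  vals <- object$feature_values[, feats, drop = FALSE]
  vals <- apply(vals, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  })
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object$averaged[, feats, drop = FALSE], rownames = "id"),
    -dplyr::all_of("id"), names_to = "feature", values_to = "attribution"
  )
  long$feature_value <- as.vector(t(vals))[
    match(paste(long$id, long$feature),
          paste(rep(object$ids, each = length(feats)), rep(feats, length(object$ids))))]
  long$feature <- factor(long$feature, levels = rev(feats))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$attribution, y = .data$feature,
                                     color = .data$feature_value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.8, size = 1.5) +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  name = "feature value\n(scaled)") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "averaged SHAP attribution (margin scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the 3-class potency confusion matrix
#'
#' @param object A `sens_potency` from [potency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_potency
#' @export
autoplot.sens_potency <- function(object, ...) {
  m <- object$counts
  df <- tibble::as_tibble(as.data.frame.table(unclass(m), stringsAsFactors = FALSE))
  names(df) <- c("predicted", "human", "n")
  lv <- c("NC", "1B", "1A")
  df$predicted <- factor(df$predicted, levels = rev(lv))
  df$human <- factor(df$human, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$human, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "human class", y = "predicted class",
                  title = sprintf("%.0f%% correct overall",
                                  100 * object$overall_accuracy)) +
    ggplot2::theme_minimal()
}
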