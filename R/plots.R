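#' @import ggplot2
NULL

#' Bar plot of binned co-expression proportions with bootstrap error bars
#'
#' @param summaries Bin-summary tibble from [bin_pairs()] or
#'   [combined_group()].
#' @return A ggplot.
#' @export
plot_bin_summary <- function(summaries) {
  ggplot(summaries, aes(x = factor(.data$label, levels = unique(.data$label)),
                        y = 100 * .data$proportion)) +
    geom_col(fill = "#4477AA", width = 0.65) +
    geom_errorbar(aes(ymin = 100 * (.data$proportion - .data$bootstrap_se),
                      ymax = 100 * (.data$proportion + .data$bootstrap_se)),
                  width = 0.2) +
    labs(x = NULL, y = "co-expressed pairs (%)") +
    theme_classic()
}

#' Randomization null distribution with the observed proportion
#'
#' @param null List from [randomization_null()].
#' @return A ggplot.
#' @export
plot_null_distribution <- function(null) {
  p <- ggplot(tibble(proportion = null$proportions), aes(.data$proportion)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    labs(x = "null co-expression proportion", y = "iterations") +
    theme_classic()
  if (!is.null(null$observed)) {
    p <- p + geom_vline(xintercept = null$observed, colour = "#CC3311",
                        linetype = 2, linewidth = 0.8)
  }
  p
}

#' Mean AUC per feature set
#'
#' @param results List of `sng_model_result` objects (named or not).
#' @return A ggplot.
#' @export
plot_feature_auc <- function(results) {
  tb <- purrr::map_dfr(results, glance)
  ggplot(tb, aes(x = stats::reorder(.data$features, .data$mean_auc),
                 y = .data$mean_auc)) +
    geom_col(fill = "#228833", width = 0.65) +
    geom_errorbar(aes(ymin = .data$mean_auc - .data$sd_auc,
                      ymax = .data$mean_auc + .data$sd_auc), width = 0.2) +
    geom_hline(yintercept = 0.5, linetype = 3) +
    coord_flip() +
    labs(x = NULL, y = "mean AUC") +
    theme_classic()
}

#' Interaction surface: predicted co-expression probability vs distance
#'
#' @param surface Tibble from [interaction_surface()].
#' @return A ggplot.
#' @export
plot_interaction_surface <- function(surface) {
  ggplot(surface, aes(.data$distance, .data$prob, colour = .data$level,
                      group = .data$level)) +
    geom_line(linewidth = 0.8) +
    geom_point(size = 1.6) +
    labs(x = "intergenic distance (bp)", y = "predicted P(co-expressed)",
         colour = "feature level") +
    theme_classic()
}

#' Module-metabolite correlation heatmap
#'
#' @param mm Tibble from [module_metabolite_correlation()].
#' @return A ggplot.
#' @export
plot_module_metabolite <- function(mm) {
  ggplot(mm, aes(.data$metabolite, .data$module, fill = .data$r)) +
    geom_tile(colour = "white") +
    geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(low = "#4477AA", mid = "white", high = "#CC3311",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' Histogram of per-repeat AUCs for a model result
#'
#' @param object An `sng_model_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sng_model_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$auc)) +
    geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$mean_auc, colour = "#CC3311", linetype = 2) +
    labs(x = "AUC per repeat", y = "repeats",
         title = paste(object$feature_set, collapse = " + ")) +
    theme_classic()
}
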