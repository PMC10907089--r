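#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_jitter labs
#'   theme_minimal autoplot scale_y_log10 geom_hline coord_flip
NULL

#' Bee-swarm style plot of Shapley feature importance
#'
#' @param attributions An `l2g_attribution` ([attribute()]).
#' @param n_top Number of features shown (default 20).
#' @return A ggplot.
#' @export
plot_importance_beeswarm <- function(attributions, n_top = 20) {
  imp <- global_importance(attributions)
  keep <- utils::head(imp$feature, n_top)
  long <- imp |>
    filter(.data$feature %in% keep) |>
    tidyr::unnest_longer("contributions", values_to = "contribution") |>
    mutate(feature = factor(.data$feature, levels = rev(keep)))
  ggplot(long, aes(x = .data$contribution, y = .data$feature)) +
    geom_jitter(height = 0.25, size = 0.4, alpha = 0.5) +
    labs(x = "Shapley contribution (log-odds)", y = NULL,
         title = "Feature importance (mean |SHAP| order)") +
    theme_minimal()
}

#' Waterfall plot of one gene's score decomposition
#'
#' @inheritParams waterfall
#' @return A ggplot.
#' @export
plot_waterfall <- function(attributions, pair_id, n_top = 10) {
  wf <- waterfall(attributions, pair_id, n_top)
  wf <- wf |> mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(wf, aes(x = .data$contribution, y = .data$feature,
                 fill = .data$contribution > 0)) +
    geom_col(show.legend = FALSE) +
    labs(x = "contribution to margin (log-odds)", y = NULL,
         title = pair_id,
         subtitle = sprintf("E[f(x)] = %.3f, f(x) = %.3f",
                            attr(wf, "base_value"), attr(wf, "margin"))) +
    theme_minimal()
}

#' Volcano plot of over-representation results
#'
#' Enrichment ratio against FDR, mirroring the usual ORA volcano display.
#'
#' @param enrichment Output of [ora()].
#' @param q_line FDR threshold line (default 0.05).
#' @return A ggplot.
#' @export
plot_enrichment_volcano <- function(enrichment, q_line = 0.05) {
  ggplot(enrichment,
         aes(x = .data$enrichment_ratio, y = -log10(pmax(.data$q, 1e-300)))) +
    geom_point(aes(colour = .data$q < q_line), show.legend = FALSE) +
    geom_hline(yintercept = -log10(q_line), linetype = 2) +
    labs(x = "enrichment ratio", y = "-log10 FDR") +
    theme_minimal()
}

#' Per-locus nomination probabilities
#'
#' @param nominations Output of [nominate()].
#' @return A ggplot of sorted top-gene probabilities coloured by tier.
#' @export
plot_nominations <- function(nominations) {
  d <- nominations |>
    arrange(dplyr::desc(.data$probability)) |>
    mutate(rank = row_number())
  ggplot(d, aes(x = .data$rank, y = .data$probability, colour = .data$tier)) +
    geom_point() +
    geom_hline(yintercept = c(0.3, 0.75), linetype = 3) +
    labs(x = "locus (sorted)", y = "top-gene probability") +
    theme_minimal()
}

#' Bee-swarm autoplot method for attributions
#' @param object An `l2g_attribution`.
#' @param ... Passed to [plot_importance_beeswarm()].
#' @method autoplot l2g_attribution
#' @export
autoplot.l2g_attribution <- function(object, ...) {
  plot_importance_beeswarm(object, ...)
}
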