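#' Plot expression profiles over the time course
#'
#' Line plot of (normalized) expression trajectories for a chosen set of
#' genes, the usual first look at whether a candidate tracks a seed
#' regulon's cell-cycle pattern.
#'
#' @param profiles An expression or profiles tibble.
#' @param genes Genes to draw; default the first 10.
#' @return A ggplot object.
#' @export
plot_expression_profiles <- function(profiles, genes = NULL) {
  profiles <- as_tibble(profiles)
  if ("degenerate" %in% names(profiles)) {
    profiles <- dplyr::filter(profiles, !.data$degenerate)
  }
  genes <- genes %||% head(profiles$gene_id, 10)
  tp <- expression_timepoints(profiles)
  long <- tidyr::pivot_longer(profiles[profiles$gene_id %in% genes, ],
                              dplyr::all_of(tp),
                              names_to = "timepoint", values_to = "value")
  long$timepoint <- factor(long$timepoint, levels = tp)
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value,
                                     group = .data$gene_id,
                                     colour = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timepoint", y = "expression", colour = "gene") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rank_result <- function(object, top_n = 20, ...) {
  dd <- head(tidy(object), top_n)
  dd$gene_id <- factor(dd$gene_id, levels = rev(dd$gene_id))
  ggplot2::ggplot(dd, ggplot2::aes(.data$weight, .data$gene_id,
                                   fill = .data$seed)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "final weight", y = NULL, fill = "seed gene") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tuning_result <- function(object, ...) {
  dd <- as_tibble(object)
  ggplot2::ggplot(dd, ggplot2::aes(factor(.data$alpha),
                                   factor(.data$cutoff),
                                   fill = .data$rank_all)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank_all),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "alpha", y = "edge-reduction cutoff",
                  fill = "held-out rank") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.window_stats <- function(object, p_max = 0.10, basemean_min = 1000,
                                  ...) {
  dd <- as_tibble(object)
  dd$significant <- dd$window_id %in%
    filter_significant_windows(object, p_max, basemean_min)
  ggplot2::ggplot(dd, ggplot2::aes(log10(.data$base_mean_bait + 1),
                                   .data$log2_fold,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = log10(basemean_min + 1),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "log10(bait base mean + 1)",
                  y = "log2 fold (bait / control)", colour = "enriched") +
    ggplot2::theme_minimal()
}
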