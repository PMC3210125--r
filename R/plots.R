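# ggplot2 figure helpers for the main result types.

#' Coverage bar chart per amplicon and sample
#' @param coverage tibble from [coverage_stats()].
#' @return a ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$amplicon_id, y = .data$mean_coverage,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average base coverage (x)",
                  fill = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Map of synonymous/non-synonymous changes along the precursor
#'
#' Non-synonymous changes are filled, synonymous ones empty; the x axis is
#' the transcript position and panels split AMPs (and samples when present).
#'
#' @param snc_map tibble from [snc_maps()].
#' @return a ggplot object.
#' @export
plot_snc_map <- function(snc_map) {
  has_sample <- "sample_id" %in% names(snc_map)
  p <- ggplot2::ggplot(snc_map,
                       ggplot2::aes(x = .data$tx_pos,
                                    y = if (has_sample) .data$sample_id else .data$amp_id,
                                    shape = .data$synonymous,
                                    colour = .data$region)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 16),
                                labels = c(`TRUE` = "synonymous",
                                           `FALSE` = "non-synonymous")) +
    ggplot2::labs(x = "transcript position (nt)", y = NULL,
                  shape = NULL, colour = "region") +
    ggplot2::theme_minimal()
  if (has_sample) p <- p + ggplot2::facet_wrap(~amp_id, scales = "free_x")
  p
}

#' Common/exclusive SNC counts per sample
#' @param ce list from [common_exclusive()].
#' @return a ggplot object.
#' @export
plot_common_exclusive <- function(ce) {
  d <- ce$by_sample %>%
    mutate(shared_partial = .data$n - .data$n_common - .data$n_exclusive) %>%
    tidyr::pivot_longer(c("n_common", "shared_partial", "n_exclusive"),
                        names_to = "class", values_to = "count") %>%
    mutate(class = factor(.data$class,
                          levels = c("n_exclusive", "shared_partial", "n_common"),
                          labels = c("exclusive", "shared (not all)", "common")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$count,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SNCs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an AMP variability grouping
#'
#' Mean SNC frequency per AMP with SD error bars, labelled with the Tukey
#' homogeneous-subset letters.
#'
#' @param object an `amp_grouping` from [anova_tukey()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.amp_grouping <- function(object, ...) {
  d <- tidy(object)
  d$amp_id <- factor(d$amp_id, levels = d$amp_id[order(-d$mean)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$amp_id, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$group,
                                    y = .data$mean + .data$sd),
                       vjust = -0.6) +
    ggplot2::labs(x = NULL, y = "SNC frequency (changes / codon)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
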