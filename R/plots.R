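#' Plot per-column site classifications along an alignment
#'
#' A one-row tile map of the [classify_sites()] labels in alignment order:
#' additive columns stand out as the hybrid signature, residual columns as
#' unexplained signal. Useful for eyeballing a candidate parent pair.
#'
#' @param sites site tibble from [classify_sites()].
#' @param drop_invariant hide INVARIANT columns (default TRUE; with them the
#'   signal columns are invisible at realistic lengths).
#' @return a ggplot object.
#' @export
plot_sites <- function(sites, drop_invariant = TRUE) {
  d <- if (drop_invariant) {
    dplyr::filter(sites, .data$label != "INVARIANT")
  } else sites
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = 1, fill = .data$label)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_brewer(palette = "Set1", drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "alignment position", y = NULL, fill = "site class") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ht_parentage <- function(object, ...) {
  d <- dplyr::count(object, .data$verdict)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$verdict, y = .data$n,
                                  fill = .data$verdict)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "samples",
                  title = "Parentage verdicts") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ht_region_summary <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[c("region", "pct_hybrid_individuals",
             "pct_localities_with_hybrids", "pct_localities_hybrid_only")],
    -"region", names_to = "statistic", values_to = "pct")
  d$statistic <- factor(
    d$statistic,
    levels = c("pct_hybrid_individuals", "pct_localities_with_hybrids",
               "pct_localities_hybrid_only"),
    labels = c("hybrid individuals", "localities with hybrids",
               "hybrid-only localities"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$pct,
                                  fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of region", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
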