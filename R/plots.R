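# ggplot2 views of the report tables.

.quadrant_palette <- c(
  SynUp = "#d95f02", SynDown = "#7570b3",
  DegUp = "#1b9e77", DegDown = "#e7298a",
  Indeterminate = "grey60"
)

#' Proteostasis scatter of ontology terms
#'
#' Mean scaled delta-abundance (x) against mean scaled delta-turnover
#' (y), one point per ontology term, colored by quadrant class; filled
#' points are significant terms. The axes' quadrants carry the
#' regulation reading: upper right synthesis up, lower right degradation
#' down, lower left synthesis down, upper left degradation up.
#'
#' @param scatter Scatter table from [build_report()] (or
#'   [tidy()][tidy.proteostasis_run] of a run).
#' @return A ggplot object.
#' @export
plot_proteostasis <- function(scatter) {
  ggplot2::ggplot(
    scatter,
    ggplot2::aes(x = .data$mean_abundance_fc, y = .data$mean_turnover_fc,
                 color = .data$regulation_class,
                 alpha = .data$significant %in% TRUE)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = .quadrant_palette, name = "class") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                name = "significant") +
    ggplot2::labs(x = "mean scaled Δabundance",
                  y = "mean scaled Δturnover") +
    ggplot2::theme_minimal()
}

#' Paired abundance/turnover bars for selected ontology terms
#'
#' One panel per term; each member protein shows its scaled abundance
#' and (when available) turnover fold change side by side.
#'
#' @param bars Bar table from [build_report()].
#' @param terms Optional character vector of term ids to show (default:
#'   all in `bars`).
#' @return A ggplot object.
#' @export
plot_ontology_bars <- function(bars, terms = NULL) {
  if (!is.null(terms)) {
    bars <- dplyr::filter(bars, .data$term_id %in% terms)
  }
  ggplot2::ggplot(
    bars,
    ggplot2::aes(x = .data$protein_id, y = .data$fc_scaled,
                 fill = .data$metric)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::geom_hline(yintercept = 0, color = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$term_id), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "scaled fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Heatmap of the percentage of proteins shared between ontology terms
#'
#' @param overlap Square matrix from [overlap_matrix()].
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(overlap) {
  df <- tibble::as_tibble(overlap, rownames = "term_a") |>
    tidyr::pivot_longer(-"term_a", names_to = "term_b",
                        values_to = "pct_shared")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term_b, y = .data$term_a,
                                   fill = .data$pct_shared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 100), name = "% shared") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_proteostasis
#' @param object A `proteostasis_run`.
#' @param ... Unused.
#' @method autoplot proteostasis_run
#' @export
autoplot.proteostasis_run <- function(object, ...) {
  plot_proteostasis(object$report$scatter)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
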