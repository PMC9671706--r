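#' Volcano plot of a DE table
#'
#' @param de DE tibble from [call_degs()].
#' @param lfc_cut,fdr_cut Thresholds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_cut = 0.5, fdr_cut = 0.001) {
  stopifnot(all(c("log2fc", "adj_p") %in% names(de)))
  if (!"status" %in% names(de)) de$status <- "not_de"
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$adj_p, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(fdr_cut), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2471a3",
                                            not_de = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enriched gene sets
#'
#' Bar lengths are `-log10` of the raw enrichment p-value; sets are shown
#' in rank order.
#'
#' @param enrichment Tibble from [enrich()].
#' @param top Number of top sets to display (default 5).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 5) {
  df <- head(enrichment, top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$p_value, 1e-300)),
                                   y = .data$set_name,
                                   fill = .data$adj_p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1e8449",
                                          `FALSE` = "grey65"),
                               name = "adj p < 0.05") +
    ggplot2::labs(x = "-log10 p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of lncRNA-mRNA correlation coefficients
#'
#' Mirrors the usual co-expression panel: tiles coloured by the Pearson
#' coefficient, blank where the FDR exceeds `fdr_max`.
#'
#' @param correlations Tibble from [correlate_pairs()].
#' @param fdr_max Tiles with `corr_fdr >=` this value are blanked.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(correlations, fdr_max = 0.001) {
  df <- correlations |>
    mutate(r_shown = ifelse(.data$corr_fdr < fdr_max, .data$r, NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mrna, y = .data$lncrna,
                                   fill = .data$r_shown)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#c0392b", mid = "white",
                                  high = "#1a5276", midpoint = 0,
                                  limits = c(-1, 1), na.value = "white",
                                  name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pipeline run
#'
#' @param object A `cerna_run`.
#' @param type One of `"volcano"`, `"enrichment"`, `"correlation"`.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @method autoplot cerna_run
#' @export
autoplot.cerna_run <- function(object, type = c("volcano", "enrichment",
                                                "correlation"), ...) {
  type <- match.arg(type)
  switch(type,
    volcano = plot_volcano(object$de, object$config$lfc_cut,
                           object$config$fdr_cut, ...),
    enrichment = plot_enrichment(object$enrichment, ...),
    correlation = plot_correlation_matrix(object$correlations,
                                          object$config$corr_fdr_max, ...))
}
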