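#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a burden fit
#'
#' One point per gene and control dataset at -log10(p), with the
#' Bonferroni threshold as a dashed line; genes ordered by their strongest
#' association.
#'
#' @param object a `kp_burden` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot kp_burden
#' @export
autoplot.kp_burden <- function(object, ...) {
  df <- object$results %>%
    filter(!is.na(p_value)) %>%
    mutate(gene = stats::reorder(gene, -log10(p_value), FUN = max))
  ggplot2::ggplot(df, ggplot2::aes(x = gene, y = -log10(p_value),
                                   colour = dataset_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$threshold),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  colour = "control dataset",
                  title = "Qualifying-variant burden per gene",
                  subtitle = paste0("dashed line: Bonferroni ",
                                    signif(object$threshold, 3))) +
    ggplot2::theme_minimal()
}

#' Plot consensus pathogenicity scores of a novel-variant report
#'
#' @param report tibble from [novel_variant_report()].
#' @return a ggplot (bar per variant, coloured by the REVEL call).
#' @export
plot_consensus_scores <- function(report) {
  df <- report %>%
    mutate(label = paste0(gene, " ", dplyr::coalesce(protein_change, cdna_change)))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(label, score), y = score,
                                   fill = dplyr::coalesce(revel_call, "n/a"))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of tools calling deleterious",
                  fill = "REVEL") +
    ggplot2::theme_minimal()
}
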