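# ggplot2 autoplot methods for hifsort result objects.

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result`.
#' @param l2fc_min,alpha Regulation thresholds used for colouring.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, l2fc_min = 1, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(called = dplyr::case_when(
      .data$padj < alpha & .data$l2fc > l2fc_min ~ "up",
      .data$padj < alpha & .data$l2fc < -l2fc_min ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(.data$l2fc, -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = attr(object, "contrast"),
                  subtitle = attr(object, "identity"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Category composition of dependence calls
#'
#' @param object A `dependence_calls` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot dependence_calls
#' @export
autoplot.dependence_calls <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$direction, fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::facet_wrap(ggplot2::vars(.data$identity)) +
    ggplot2::labs(y = "proportion of Vhl-dependent genes", x = NULL) +
    ggplot2::theme_minimal()
}

#' Scaled program scores by genotype
#'
#' @param object A `scaled_scores` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot scaled_scores
#' @export
autoplot.scaled_scores <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$genotype, .data$scaled,
                               fill = .data$timepoint)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = c(0, attr(object, "direction") == "up"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(y = "scaled program score", x = NULL) +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param object An `enrichment_result`.
#' @param top Number of top sets to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$padj),
                                   stats::reorder(.data$set, -.data$padj),
                                   size = .data$n_overlap)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}

#' GSEA running-sum plot
#'
#' @param object A `gsea_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  ggplot2::ggplot(object$running, ggplot2::aes(.data$rank, .data$running_es)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_rug(data = dplyr::filter(object$running, .data$in_set),
                      sides = "b", length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                     object$es, object$nes, object$p)) +
    ggplot2::theme_minimal()
}

#' Tagged-neighbor frequency distributions per mouse
#'
#' @param object A `neighbor_stats` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot neighbor_stats
#' @export
autoplot.neighbor_stats <- function(object, ...) {
  df <- object$per_mouse |>
    tidyr::pivot_longer(dplyr::starts_with("freq_"), names_to = "bin",
                        names_prefix = "freq_", values_to = "n") |>
    dplyr::group_by(.data$mouse) |>
    dplyr::mutate(prop = .data$n / sum(.data$n),
                  bin = factor(.data$bin, levels = unique(.data$bin))) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$prop, group = .data$mouse)) +
    ggplot2::geom_col(position = "dodge", fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$mouse)) +
    ggplot2::labs(x = "tagged neighbors within radius", y = "proportion of tagged cells") +
    ggplot2::theme_minimal()
}
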