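# broom-style tidiers for hifsort result objects.

#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(contrast = attr(x, "contrast"),
                  identity = attr(x, "identity"))
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(contrast = attr(x, "contrast"),
                 identity = attr(x, "identity"),
                 n_genes = nrow(x),
                 n_up = sum(x$l2fc > 1 & x$padj < 0.05, na.rm = TRUE),
                 n_down = sum(x$l2fc < -1 & x$padj < 0.05, na.rm = TRUE),
                 n_flagged = sum(x$flag != ""))
}

#' @method tidy dependence_calls
#' @export
tidy.dependence_calls <- function(x, ...) tibble::as_tibble(x)

#' @method glance dependence_calls
#' @export
glance.dependence_calls <- function(x, ...) {
  x |>
    dplyr::count(.data$identity, .data$direction, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
}

#' @method tidy manova_wilks
#' @export
tidy.manova_wilks <- function(x, ...) {
  if (!is.null(x$pairwise)) return(x$pairwise)
  tibble::tibble(lambda = x$lambda, f = x$f, df1 = x$df1, df2 = x$df2, p = x$p)
}

#' @method glance manova_wilks
#' @export
glance.manova_wilks <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, f = x$f, df1 = x$df1, df2 = x$df2, p = x$p)
}

#' @method tidy kw_dunn
#' @export
tidy.kw_dunn <- function(x, ...) x$pairwise

#' @method glance kw_dunn
#' @export
glance.kw_dunn <- function(x, ...) {
  tibble::tibble(h = x$h, df = x$df, p = x$p, n_pairs = nrow(x$pairwise))
}

#' @method tidy gsea_result
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::tibble(es = x$es, nes = x$nes, p = x$p, size = x$size,
                 n_perm = x$n_perm)
}

#' @method glance gsea_result
#' @export
glance.gsea_result <- tidy.gsea_result

#' @method tidy scaled_scores
#' @export
tidy.scaled_scores <- function(x, ...) tibble::as_tibble(x)

#' @method glance scaled_scores
#' @export
glance.scaled_scores <- function(x, ...) {
  x |>
    dplyr::group_by(.data$genotype, .data$timepoint) |>
    dplyr::summarise(median_scaled = stats::median(.data$scaled),
                     n_cells = dplyr::n(), .groups = "drop")
}
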