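#' Cell-level quality-control parameters
#'
#' Thresholds follow the standard filters for droplet scRNA-seq of renal
#' tubular cells: detected genes per cell strictly greater than
#' `min_genes`, mitochondrial read fraction strictly below `max_mito_fraction`
#' (set high because proximal tubular cells are mitochondria-rich), and
#' detected genes strictly below `max_genes_factor` times the per-sample
#' (per-mouse) median of detected genes. All thresholds are strict
#' inequalities and are applied jointly against pre-filter medians.
#'
#' @param min_genes Minimum detected genes per cell (exclusive; default 200).
#' @param max_mito_fraction Maximum mitochondrial read fraction (exclusive;
#'   default 0.5).
#' @param max_genes_factor Doublet guard: cells with detected genes >=
#'   `max_genes_factor` x per-sample median are removed (default 3).
#' @param excluded_features Gene ids dropped from the matrix before filtering
#'   (e.g. features with ambiguous allele mapping).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200, max_mito_fraction = 0.5,
                      max_genes_factor = 3, excluded_features = character()) {
  if (max_mito_fraction <= 0 || max_mito_fraction > 1) {
    stop_hifsort("max_mito_fraction must be in (0, 1]")
  }
  if (max_genes_factor <= 1) stop_hifsort("max_genes_factor must be > 1")
  structure(list(min_genes = min_genes, max_mito_fraction = max_mito_fraction,
                 max_genes_factor = max_genes_factor,
                 excluded_features = excluded_features),
            class = "qc_params")
}

#' Apply cell-level quality filters
#'
#' Retains cells with detected genes `> min_genes`, mitochondrial fraction
#' `< max_mito_fraction`, and detected genes `< max_genes_factor x median`
#' where the median of detected genes is computed per sample (mouse) before
#' any cell is removed. The three filters are applied jointly, not
#' sequentially.
#'
#' @param m A [cell_matrix()] with `gene_meta$mito_flag` populated.
#' @param params A [qc_params()].
#' @return The filtered `cell_matrix`, with a `qc_removed` attribute: a tibble
#'   of per-filter removal counts (a cell failing several filters is counted
#'   under each).
#' @export
apply_qc <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "cell_matrix"))
  if (length(params$excluded_features) > 0) {
    keep_g <- !(m$gene_meta$gene_id %in% params$excluded_features)
    m$counts <- m$counts[keep_g, , drop = FALSE]
    m$gene_meta <- m$gene_meta[keep_g, , drop = FALSE]
  }
  n_genes <- Matrix::colSums(m$counts > 0)
  total <- Matrix::colSums(m$counts)
  mito <- Matrix::colSums(m$counts[m$gene_meta$mito_flag, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)

  med <- tapply(n_genes, m$cell_meta$mouse, stats::median)
  med_per_cell <- as.numeric(med[as.character(m$cell_meta$mouse)])

  pass_min <- n_genes > params$min_genes
  pass_mito <- mito_frac < params$max_mito_fraction
  pass_max <- n_genes < params$max_genes_factor * med_per_cell
  keep <- pass_min & pass_mito & pass_max

  removed <- tibble::tibble(
    filter = c("min_genes", "max_mito_fraction", "max_genes_factor"),
    n_removed = c(sum(!pass_min), sum(!pass_mito), sum(!pass_max))
  )
  if (!any(keep)) warn_hifsort("all %d cells removed by QC", length(keep))
  out <- subset_cells(m, keep)
  attr(out, "qc_removed") <- removed
  attr(out, "n_input_cells") <- length(keep)
  out
}
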