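#' Aggregate cells into per-mouse pseudo-bulk samples
#'
#' Sums raw counts over each mouse's cells within one PT identity, so that
#' mice -- not cells -- act as biological replicates in downstream testing.
#'
#' @param m A [cell_matrix()] whose `cell_meta` carries `identity`.
#' @param identity The PT identity (stratum) to aggregate; `NULL` uses all
#'   cells.
#' @param min_cells Mice contributing fewer cells than this to the stratum
#'   are excluded with a warning (default 10).
#' @return A `pseudobulk` object: list with `counts` (genes x samples integer
#'   matrix), `sample_meta` (tibble: `sample`, `mouse`, `sex`, `genotype`,
#'   `timepoint`, `identity`, `n_cells`) and `size_factors` (NULL until
#'   [estimate_size_factors()]).
#' @export
aggregate_pseudobulk <- function(m, identity = NULL, min_cells = 10) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  if (!is.null(identity)) {
    assert_columns(meta, "identity", "cell_meta")
    keep <- meta$identity == identity
    m <- subset_cells(m, keep)
    meta <- m$cell_meta
  }
  if (nrow(meta) == 0) stop_hifsort("no cells in stratum '%s'", identity %||% "all")

  mice <- unique(meta$mouse)
  ncell <- table(meta$mouse)[mice]
  drop <- mice[ncell < min_cells]
  if (length(drop) > 0) {
    warn_hifsort("excluding %d mouse/mice with < %d cells in stratum: %s",
                 length(drop), min_cells, paste(drop, collapse = ", "))
    mice <- setdiff(mice, drop)
  }
  if (length(mice) == 0) stop_hifsort("no mouse retains >= %d cells", min_cells)

  cols <- lapply(mice, function(mo) {
    Matrix::rowSums(m$counts[, meta$mouse == mo, drop = FALSE])
  })
  counts <- do.call(cbind, cols)
  colnames(counts) <- mice
  sample_meta <- meta |>
    dplyr::distinct(.data$mouse, .data$sex, .data$genotype, .data$timepoint) |>
    dplyr::filter(.data$mouse %in% mice) |>
    dplyr::arrange(match(.data$mouse, mice)) |>
    dplyr::mutate(sample = .data$mouse, identity = identity %||% "all",
                  n_cells = as.integer(ncell[.data$mouse]))
  structure(list(counts = counts, sample_meta = sample_meta,
                 size_factors = NULL),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d samples (identity: %s)\n",
              nrow(x$counts), ncol(x$counts), x$sample_meta$identity[1]))
  print(table(x$sample_meta$genotype, x$sample_meta$timepoint))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across genes of the ratio
#' of its count to the per-gene geometric mean, using only genes with
#' strictly positive counts in every sample; factors are then normalized to
#' geometric mean 1. Falls back to total-count ratios (with a warning) when
#' no gene is positive everywhere.
#'
#' @param pb A `pseudobulk` object (or bare genes x samples matrix).
#' @return The `pseudobulk` with `size_factors` filled (or, for a bare
#'   matrix, the named factor vector).
#' @export
estimate_size_factors <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warn_hifsort("no gene positive in all samples; using total-count ratios")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
  } else {
    logc <- log(counts[all_pos, , drop = FALSE])
    loggm <- rowMeans(logc)
    sf <- apply(logc, 2, function(x) exp(stats::median(x - loggm)))
    sf <- sf / exp(mean(log(sf)))
  }
  if (inherits(pb, "pseudobulk")) {
    pb$size_factors <- sf
    pb
  } else {
    sf
  }
}
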