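#' Derive marker genes from a reference differential-expression table
#'
#' A gene is accepted as a marker when, in the reference comparison of the
#' marked cells against all others, its log2 fold change exceeds `l2fc_min`,
#' it is expressed in more than `pct_in_min` of the cells it marks, and in
#' less than `pct_out_max` of the cells it does not mark. All three
#' inequalities are strict.
#'
#' @param ref_de Tibble with columns `gene`, `l2fc`, `pct_in`, `pct_out`.
#' @param l2fc_min,pct_in_min,pct_out_max Thresholds (defaults 1.0, 0.5, 0.2).
#' @return Tibble of passing rows; warns if empty.
#' @export
derive_markers <- function(ref_de, l2fc_min = 1.0, pct_in_min = 0.5,
                           pct_out_max = 0.2) {
  assert_columns(ref_de, c("gene", "l2fc", "pct_in", "pct_out"), "ref_de")
  out <- dplyr::filter(tibble::as_tibble(ref_de),
                       .data$l2fc > l2fc_min,
                       .data$pct_in > pct_in_min,
                       .data$pct_out < pct_out_max)
  if (nrow(out) == 0) warn_hifsort("no genes pass the marker thresholds")
  out
}

#' Rank-ceiling signature scores (UCell-style)
#'
#' Per cell, genes are ranked by descending expression (average ranks for
#' ties, so unexpressed genes share the bottom average rank); ranks of
#' signature genes are clipped at `max_rank + 1`; the score is the normalized
#' Mann-Whitney U statistic
#' `1 - (sum(min(r_i, max_rank+1)) - n(n+1)/2) / (n * max_rank)`,
#' which lies in `[0, 1]` (up to a `(n-1)/(2 max_rank)` floor when every
#' signature gene is clipped) and is comparable across signatures within a
#' cell. Being rank-based it is invariant to any monotone transform of the
#' expression values.
#'
#' @param m A [cell_matrix()].
#' @param markers Marker tibble with columns `set`, `gene` and optionally
#'   `sex` (`NA` rows are unisex). Sex-specific rows are only scored in cells
#'   of the matching sex; a set with sex-specific rows is reported as one
#'   score column per set, computed from the sex-matched gene list.
#' @param max_rank Rank ceiling (default 1500); must be smaller than the
#'   number of genes.
#' @return A `score_table` tibble: `cell_id` plus one column per marker set.
#' @export
rank_signature_score <- function(m, markers, max_rank = 1500) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.character(markers)) markers <- tibble::tibble(set = "signature",
                                                       gene = markers)
  assert_columns(markers, c("set", "gene"), "markers")
  if (!"sex" %in% names(markers)) markers$sex <- NA_character_
  present <- markers$gene %in% m$gene_meta$gene_id
  if (any(!present)) {
    warn_hifsort("%d marker genes absent from matrix; dropped", sum(!present))
    markers <- markers[present, , drop = FALSE]
  }
  if (nrow(markers) == 0) stop_hifsort("no marker genes present in matrix")
  G <- nrow(m$counts)
  if (max_rank >= G) stop_hifsort("max_rank must be < number of genes (%d)", G)
  n_per <- table(paste(markers$set, markers$sex))
  if (any(n_per > max_rank)) stop_hifsort("a signature is larger than max_rank")

  sets <- sort(unique(markers$set))
  gene_index <- setNames(seq_len(G), m$gene_meta$gene_id)
  sex_vec <- m$cell_meta$sex
  X <- m$counts
  ncell <- ncol(X)
  scores <- matrix(NA_real_, nrow = ncell, ncol = length(sets),
                   dimnames = list(NULL, sets))
  ceiling_rank <- max_rank + 1
  chunk <- 2000L
  for (start in seq(1, ncell, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ncell)
    dense <- as.matrix(X[, idx, drop = FALSE])
    ranks <- apply(dense, 2, function(x) rank(-x, ties.method = "average"))
    for (s in sets) {
      rows <- markers[markers$set == s, , drop = FALSE]
      for (j in seq_along(idx)) {
        gl <- rows$gene[is.na(rows$sex) | rows$sex == sex_vec[idx[j]]]
        n <- length(gl)
        if (n == 0) next
        r <- pmin(ranks[gene_index[gl], j], ceiling_rank)
        scores[idx[j], s] <- 1 - (sum(r) - n * (n + 1) / 2) / (n * max_rank)
      }
    }
  }
  out <- tibble::as_tibble(scores)
  out <- dplyr::bind_cols(tibble::tibble(cell_id = m$cell_meta$cell_id), out)
  structure(out, class = c("score_table", class(out)),
            method = "rank_ceiling", max_rank = max_rank)
}

#' Assign cell types by highest signature score
#'
#' Each cell receives the label of the marker set with the highest
#' rank-ceiling score. Exact ties are broken lexicographically and flagged.
#'
#' @param scores A `score_table` from [rank_signature_score()].
#' @return Tibble `cell_id`, `identity`, `tie` (logical).
#' @export
assign_cell_type <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  mat <- as.matrix(scores[, setdiff(names(scores), "cell_id"), drop = FALSE])
  labs <- colnames(mat)[order(colnames(mat))]
  mat <- mat[, labs, drop = FALSE]
  best <- apply(mat, 1, function(x) which.max(x))  # first max = lexicographic
  tie <- apply(mat, 1, function(x) sum(x == max(x, na.rm = TRUE), na.rm = TRUE) > 1)
  tibble::tibble(cell_id = scores$cell_id, identity = labs[best], tie = tie)
}

#' Binned-control module score
#'
#' The classic module score: genes are binned into `n_bins` equal-frequency
#' bins by their average log-normalized expression across all cells; for each
#' signature gene, `n_ctrl` control genes are sampled (without replacement,
#' seeded) from the same bin; the per-cell score is the mean log-normalized
#' expression of the signature genes minus that of the pooled (unique)
#' control genes.
#'
#' @param m A [cell_matrix()].
#' @param gene_set Character vector of gene ids.
#' @param n_bins Number of expression bins (default 100).
#' @param n_ctrl Control genes sampled per signature gene (default 50). If a
#'   bin holds fewer than `n_ctrl` genes they are sampled with replacement
#'   with a warning (the pooled control set keeps unique genes).
#' @param seed Integer seed for the control draw.
#' @return A `score_table` tibble (`cell_id`, `score`) with the control draw
#'   recorded in `attr(, "controls")`.
#' @export
binned_control_score <- function(m, gene_set, n_bins = 100, n_ctrl = 50,
                                 seed = 1L) {
  stopifnot(inherits(m, "cell_matrix"))
  gene_set <- intersect(gene_set, m$gene_meta$gene_id)
  if (length(gene_set) == 0) stop_hifsort("gene_set empty after intersection")
  dat <- lognorm_counts(m$counts)
  avg <- Matrix::rowMeans(dat)
  n_bins_eff <- min(n_bins, length(avg))
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins_eff)
  names(bin) <- rownames(dat)

  set.seed(seed)
  controls <- character()
  warned <- FALSE
  for (g in gene_set) {
    pool <- names(bin)[bin == bin[g]]
    if (length(pool) < n_ctrl) {
      if (!warned) {
        warn_hifsort("bin smaller than n_ctrl (%d < %d); sampling with replacement",
                     length(pool), n_ctrl)
        warned <- TRUE
      }
      controls <- c(controls, sample(pool, n_ctrl, replace = TRUE))
    } else {
      controls <- c(controls, sample(pool, n_ctrl, replace = FALSE))
    }
  }
  controls <- unique(controls)
  sig_mean <- Matrix::colMeans(dat[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(dat[controls, , drop = FALSE])
  out <- tibble::tibble(cell_id = m$cell_meta$cell_id,
                        score = as.numeric(sig_mean - ctrl_mean))
  structure(out, class = c("score_table", class(out)),
            method = "binned_control", controls = controls,
            n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
}

#' Assign PT class from a Module A score
#'
#' Cells whose binned-control Module A score is strictly greater than
#' `threshold` are Class A; all others are Class B.
#'
#' @param score_a A `score_table` from [binned_control_score()] on the
#'   Module A gene set.
#' @param threshold Class boundary (default 0.125).
#' @return Tibble `cell_id`, `class`.
#' @export
assign_pt_class <- function(score_a, threshold = 0.125) {
  assert_columns(score_a, c("cell_id", "score"), "score_a")
  tibble::tibble(cell_id = score_a$cell_id,
                 class = ifelse(score_a$score > threshold, "A", "B"))
}

#' Annotate cells with PT identity (cell type x class)
#'
#' Convenience wrapper: rank-ceiling scoring + argmax cell type, Module A
#' binned-control scoring + class threshold, identity = `"<type>_<class>"`.
#'
#' @inheritParams rank_signature_score
#' @param module_a Module A gene set.
#' @param max_rank Rank ceiling for type scores.
#' @param class_threshold Module A threshold.
#' @param n_bins,n_ctrl,seed Passed to [binned_control_score()].
#' @return The `cell_matrix` with `identity`, `cell_type`, `pt_class` and
#'   `tie` columns filled in `cell_meta`.
#' @export
annotate_cells <- function(m, markers, module_a, max_rank = 1500,
                           class_threshold = 0.125, n_bins = 100,
                           n_ctrl = 50, seed = 1L) {
  ts <- rank_signature_score(m, markers, max_rank = max_rank)
  typ <- assign_cell_type(ts)
  cls <- assign_pt_class(binned_control_score(m, module_a, n_bins = n_bins,
                                              n_ctrl = n_ctrl, seed = seed),
                         threshold = class_threshold)
  m$cell_meta <- m$cell_meta |>
    dplyr::select(-dplyr::any_of(c("identity", "cell_type", "pt_class", "tie"))) |>
    dplyr::left_join(dplyr::rename(typ, cell_type = "identity"), by = "cell_id") |>
    dplyr::left_join(dplyr::rename(cls, pt_class = "class"), by = "cell_id") |>
    dplyr::mutate(identity = paste(.data$cell_type, .data$pt_class, sep = "_"))
  m
}
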