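# Reference-anchored program scoring and bulk-sample scoring.

#' Score a gene program per identity and scale to reference anchors
#'
#' Raw binned-control scores are computed separately within each PT
#' identity; within each identity the scores are affinely rescaled so the
#' median of the reference cells is exactly 0 and the median of the target
#' cells is exactly +1 (up programs) or -1 (down programs); identities are
#' amalgamated after scaling. Anchor cohorts can be restricted by timepoint
#' (e.g. reference "ConKO early", target "VKO late").
#'
#' @param m An annotated [cell_matrix()] (`cell_meta$identity` present).
#' @param program Either a character vector of genes used for every
#'   identity, or a named list of per-identity gene vectors.
#' @param direction `"up"` or `"down"`.
#' @param anchor_ref,anchor_target Anchor cohorts: a genotype name, or a
#'   list `list(genotype=, timepoint=)`.
#' @param identities Identities to score (default: all with program genes).
#' @param n_bins,n_ctrl,seed Passed to [binned_control_score()].
#' @return A `scaled_scores` tibble: `cell_id`, `identity`, `genotype`,
#'   `timepoint`, `raw`, `scaled`, plus the per-identity anchors in
#'   `attr(, "anchors")`. Identities whose target and reference medians
#'   coincide are skipped with a warning.
#' @export
score_and_scale <- function(m, program, direction = c("up", "down"),
                            anchor_ref = "ConKO", anchor_target = "VKO",
                            identities = NULL, n_bins = 100, n_ctrl = 50,
                            seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "cell_matrix"))
  assert_columns(m$cell_meta, "identity", "cell_meta")
  norm_anchor <- function(a) if (is.list(a)) a else list(genotype = a, timepoint = NULL)
  ref <- norm_anchor(anchor_ref); tgt <- norm_anchor(anchor_target)
  ids <- identities %||% sort(unique(m$cell_meta$identity))
  dirsign <- if (direction == "up") 1 else -1

  res <- list(); anchors <- list()
  for (id in ids) {
    genes <- if (is.list(program)) program[[id]] else program
    if (is.null(genes) || length(genes) == 0) next
    sub <- subset_cells(m, m$cell_meta$identity == id)
    if (ncol(sub$counts) == 0) next
    sc <- binned_control_score(sub, genes, n_bins = n_bins, n_ctrl = n_ctrl,
                               seed = derive_seed(seed, id))
    meta <- sub$cell_meta
    in_cohort <- function(a) {
      ok <- meta$genotype == a$genotype
      if (!is.null(a$timepoint)) ok <- ok & meta$timepoint == a$timepoint
      ok
    }
    m_ref <- stats::median(sc$score[in_cohort(ref)])
    m_tgt <- stats::median(sc$score[in_cohort(tgt)])
    if (!is.finite(m_ref) || !is.finite(m_tgt) || m_tgt == m_ref) {
      warn_hifsort("identity %s: anchor medians undefined or equal; skipped", id)
      next
    }
    scaled <- dirsign * (sc$score - m_ref) / (m_tgt - m_ref)
    res[[id]] <- tibble::tibble(cell_id = meta$cell_id, identity = id,
                                genotype = meta$genotype,
                                timepoint = meta$timepoint,
                                raw = sc$score, scaled = scaled)
    anchors[[id]] <- tibble::tibble(identity = id, median_ref = m_ref,
                                    median_target = m_tgt, dirsign = dirsign)
  }
  if (length(res) == 0) stop_hifsort("no identity could be scored")
  out <- dplyr::bind_rows(res)
  structure(out, class = c("scaled_scores", class(out)),
            anchors = dplyr::bind_rows(anchors), direction = direction)
}

#' Dedifferentiation score: own-marker expression per PT cell type
#'
#' PT S1, S2 and S3 cells are scored (binned-control) for their own
#' cell-type marker set; S2/S3 cells use the sex-matched list. Reduced
#' own-marker scores relative to control cells indicate dedifferentiation.
#'
#' @param m An annotated [cell_matrix()] (`cell_type` or `identity` in
#'   `cell_meta`).
#' @param markers Marker tibble (`set`, `sex`, `gene`) as produced by the
#'   simulator or read from TSV.
#' @inheritParams score_and_scale
#' @return Tibble `cell_id`, `cell_type`, `sex`, `genotype`, `timepoint`,
#'   `score`; per-genotype medians in `attr(, "genotype_medians")`.
#' @export
dedifferentiation_score <- function(m, markers, n_bins = 100, n_ctrl = 50,
                                    seed = 1L) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  if (!"cell_type" %in% names(meta)) {
    assert_columns(meta, "identity", "cell_meta")
    meta$cell_type <- sub("_[AB]$", "", meta$identity)
  }
  if (!"sex" %in% names(markers)) markers$sex <- NA_character_
  res <- list()
  for (ct in intersect(unique(meta$cell_type), unique(markers$set))) {
    sexes <- unique(markers$sex[markers$set == ct])
    for (sx in sexes) {
      gl <- markers$gene[markers$set == ct &
                           (is.na(markers$sex) == is.na(sx)) &
                           (is.na(sx) | markers$sex %in% sx)]
      keep <- meta$cell_type == ct & (is.na(sx) | meta$sex == sx)
      if (!any(keep) || length(gl) == 0) next
      sub <- subset_cells(m, keep)
      sc <- binned_control_score(sub, gl, n_bins = n_bins, n_ctrl = n_ctrl,
                                 seed = derive_seed(seed, paste(ct, sx)))
      res[[paste(ct, sx)]] <- tibble::tibble(
        cell_id = sub$cell_meta$cell_id, cell_type = ct,
        sex = sub$cell_meta$sex, genotype = sub$cell_meta$genotype,
        timepoint = sub$cell_meta$timepoint, score = sc$score)
    }
  }
  if (length(res) == 0) stop_hifsort("no cell type with a marker set")
  out <- dplyr::bind_rows(res)
  med <- out |>
    dplyr::group_by(.data$cell_type, .data$genotype) |>
    dplyr::summarise(median_score = stats::median(.data$score), .groups = "drop")
  structure(out, genotype_medians = med)
}

#' Summed z-score of a gene set in bulk samples
#'
#' Each gene's expression is z-scaled across all samples (mean 0, SD 1);
#' per-sample scores are the sums of the scaled values over the set genes.
#' Zero-variance genes are dropped with a warning. Because of the z-scaling
#' the score is invariant to per-gene affine transforms of the input.
#'
#' @param bulk Genes x samples numeric matrix (rownames = gene ids), or a
#'   data frame whose first column is the gene id.
#' @param gene_set Non-empty character vector.
#' @param groups Optional per-sample group labels; if given, a
#'   Kruskal-Wallis test on the scores (with Bonferroni-adjusted pairwise
#'   Dunn comparisons) is attached as `attr(, "test")`.
#' @return Tibble `sample`, `score`.
#' @export
score_bulk_samples <- function(bulk, gene_set, groups = NULL) {
  if (length(gene_set) == 0) stop_hifsort("gene_set is empty")
  if (is.data.frame(bulk)) {
    mat <- as.matrix(bulk[, -1, drop = FALSE])
    rownames(mat) <- as.character(bulk[[1]])
  } else {
    mat <- as.matrix(bulk)
  }
  if (ncol(mat) < 2) stop_hifsort("need >= 2 samples")
  genes <- intersect(gene_set, rownames(mat))
  if (length(genes) == 0) stop_hifsort("no gene_set genes in matrix")
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warn_hifsort("dropping %d zero-variance gene(s)", sum(sds == 0))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0) stop_hifsort("all set genes have zero variance")
  }
  z <- t(scale(t(sub)))
  out <- tibble::tibble(sample = colnames(mat) %||% as.character(seq_len(ncol(mat))),
                        score = unname(colSums(z)))
  if (!is.null(groups)) {
    attr(out, "test") <- compare_medians(out$score, groups)
  }
  out
}

#' Hypergeometric enrichment of a marker set in a gene set
#'
#' Upper-tail probability of observing at least the actual overlap between
#' `query` (e.g. HIF2A-specific downregulated genes) and `markers` (e.g. the
#' pooled PT marker genes), drawing from `universe`.
#'
#' @param query,markers Character vectors (subsets of `universe`).
#' @param universe All genes considered.
#' @return List with `overlap`, `expected`, `p`.
#' @export
enrichment_of_markers <- function(query, markers, universe) {
  if (length(universe) == 0) stop_hifsort("universe is empty")
  query <- intersect(query, universe)
  markers <- intersect(markers, universe)
  k <- length(intersect(query, markers))
  p <- stats::phyper(k - 1, length(markers), length(universe) - length(markers),
                     length(query), lower.tail = FALSE)
  list(overlap = k,
       expected = length(markers) * length(query) / length(universe),
       p = p)
}
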