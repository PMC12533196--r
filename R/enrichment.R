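# Over-representation analysis and permutation gene-set enrichment.

#' Read / write gene-set collections in GMT format
#'
#' Reading delegates to `fgsea::gmtPathways`; writing emits the standard
#' tab-separated `name<TAB>description<TAB>gene...` lines.
#'
#' @param path GMT file path.
#' @return For `read_gmt`, a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_hifsort("file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Size-bound filtering shared by ora().
filter_collection <- function(collection, universe, min_size, max_size) {
  sets <- lapply(collection, intersect, y = universe)
  keep <- vapply(sets, length, integer(1))
  sets[keep >= min_size & keep <= max_size]
}

#' Over-representation analysis (one-sided hypergeometric)
#'
#' For each gene set the one-sided Fisher / hypergeometric upper-tail
#' probability of the observed overlap with the query is computed on the
#' 2x2 table against the universe; p values are BH-adjusted across the
#' tested sets. Sets outside the size bounds (after intersection with the
#' universe) are excluded before testing.
#'
#' @param query Non-empty character vector (subset of `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene ids.
#' @param min_size,max_size Inclusive size bounds applied to
#'   `|set -intersect- universe|` (defaults 50 and 1000). Use
#'   `min_size = 1, max_size = Inf` to disable.
#' @return An `enrichment_result` tibble: `set`, `n_set`, `n_overlap`,
#'   `overlap_genes` (list-column), `p`, `padj`, ordered by `p`.
#' @export
ora <- function(query, collection, universe, min_size = 50, max_size = 1000) {
  if (length(query) == 0) stop_hifsort("query set is empty")
  query <- intersect(query, universe)
  sets <- filter_collection(collection, universe, min_size, max_size)
  if (length(sets) == 0) stop_hifsort("no set within size bounds")
  N <- length(universe); nq <- length(query)
  rows <- purrr::imap(sets, function(g, nm) {
    ov <- intersect(query, g)
    k <- length(ov); K <- length(g)
    tibble::tibble(set = nm, n_set = K, n_overlap = k,
                   overlap_genes = list(ov),
                   p = stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(padj = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::arrange(.data$p)
  structure(out, class = c("enrichment_result", class(out)))
}

# Weighted Kolmogorov-Smirnov running sum (weight exponent 1 on |stat|).
# Returns the signed maximum deviation.
gsea_es <- function(ord_stats, in_set) {
  nr <- sum(abs(ord_stats[in_set]))
  n_miss <- length(ord_stats) - sum(in_set)
  if (nr == 0 || n_miss == 0) return(NA_real_)
  steps <- ifelse(in_set, abs(ord_stats) / nr, -1 / n_miss)
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Permutation gene-set enrichment on a ranked list
#'
#' Genes are ordered by decreasing statistic (e.g. L2FC); the enrichment
#' score is the signed maximum of the weighted Kolmogorov-Smirnov running
#' sum with weight exponent 1 on the absolute statistic. The null is built
#' by drawing random gene sets of the same size (gene-label permutation,
#' seeded); NES = ES / mean(|null ES| of the same sign), and the two-sided
#' permutation p value is `(1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`.
#'
#' @param stats_vec Named numeric vector, gene -> ranking statistic; no
#'   duplicate names.
#' @param gene_set Character vector; at least 5 members must intersect the
#'   ranked genes.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A `gsea_result` list: `es`, `nes`, `p`, `n_leading`, `size`,
#'   `running` (tibble for plotting).
#' @export
gsea <- function(stats_vec, gene_set, n_perm = 10000, seed = 1L) {
  if (anyDuplicated(names(stats_vec))) stop_hifsort("duplicate gene names in ranking")
  ord <- order(stats_vec, decreasing = TRUE)
  s <- stats_vec[ord]
  in_set <- names(s) %in% gene_set
  size <- sum(in_set)
  if (size < 5) stop_hifsort("gene set intersects ranked list in %d genes (< 5)", size)
  es <- gsea_es(s, in_set)

  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(s), size)
    f <- logical(length(s)); f[idx] <- TRUE
    gsea_es(s, f)
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)

  nr <- sum(abs(s[in_set]))
  steps <- ifelse(in_set, abs(s) / nr, -1 / (length(s) - size))
  running <- tibble::tibble(rank = seq_along(s), running_es = cumsum(steps),
                            in_set = in_set)
  structure(list(es = es, nes = nes, p = p, size = size,
                 n_perm = n_perm, running = running),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.3f, NES = %.3f, p = %.4g (set size %d, %d perms)\n",
              x$es, x$nes, x$p, x$size, x$n_perm))
  invisible(x)
}

#' Average member log2 fold change of a gene set
#'
#' Pools, over the supplied identities, the L2FC values of set members in
#' the identities where the member is Vhl-regulated, and averages them
#' (used to colour enrichment tiles by magnitude of change).
#'
#' @param gene_set Character vector.
#' @param de_list List of `de_result` tibbles (one per identity).
#' @param regulated_list List of [call_regulated()] tibbles aligned with
#'   `de_list`; members enter the pool only in identities where regulated.
#' @return List `mean_l2fc`, `n_values`; `mean_l2fc` is `NA` (with a
#'   warning) when no member is regulated anywhere.
#' @export
average_member_l2fc <- function(gene_set, de_list, regulated_list) {
  stopifnot(length(de_list) == length(regulated_list))
  vals <- numeric()
  for (i in seq_along(de_list)) {
    reg <- intersect(gene_set, regulated_list[[i]]$gene)
    if (length(reg) == 0) next
    vals <- c(vals, de_list[[i]]$l2fc[match(reg, de_list[[i]]$gene)])
  }
  if (length(vals) == 0) {
    warn_hifsort("no set member regulated in any identity")
    return(list(mean_l2fc = NA_real_, n_values = 0L))
  }
  list(mean_l2fc = mean(vals), n_values = length(vals))
}

#' Ward clustering of enriched terms by member-gene L2FC profiles
#'
#' Hierarchically clusters significant terms on the Euclidean distances of
#' their average-L2FC profiles using Ward's method (`ward.D2`); a plain
#' ordering utility for heatmap display.
#'
#' @param profile Terms x features numeric matrix (e.g. average member L2FC
#'   per contrast).
#' @return An `hclust` object.
#' @export
cluster_terms <- function(profile) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 2) stop_hifsort("need >= 2 terms to cluster")
  stats::hclust(stats::dist(profile, method = "euclidean"), method = "ward.D2")
}
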