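#' Construct a cell matrix container
#'
#' A `cell_matrix` bundles a genes-by-cells sparse count matrix with per-cell
#' and per-gene metadata tibbles. All downstream stages (QC, annotation,
#' pseudo-bulking, scoring) operate on this container.
#'
#' @param counts Non-negative integer matrix (genes x cells); dense or
#'   `Matrix` sparse. Dimnames supply gene and cell ids unless given
#'   explicitly in the metadata.
#' @param cell_meta Tibble with one row per cell. Must contain `cell_id`,
#'   `mouse`, `sex` (`"M"`/`"F"`), `genotype` and `timepoint`; an optional
#'   `identity` column carries assigned PT identities.
#' @param gene_meta Tibble with one row per gene: `gene_id` plus an optional
#'   logical `mito_flag` marking mitochondrially encoded genes. If absent,
#'   `mito_flag` is derived from `mito_prefix`.
#' @param mito_prefix Character vector of gene-id prefixes treated as
#'   mitochondrial when `gene_meta$mito_flag` is missing (default `"mt-"`).
#'
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_meta = NULL,
                        mito_prefix = "mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop_hifsort("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop_hifsort("counts must be integers")

  cell_meta <- tibble::as_tibble(cell_meta)
  assert_columns(cell_meta, c("cell_id", "mouse", "sex", "genotype", "timepoint"),
                 "cell_meta")
  if (anyDuplicated(cell_meta$cell_id)) {
    stop_hifsort("duplicate cell_ids; rename before constructing (e.g. suffix the sample)")
  }
  if (ncol(counts) != nrow(cell_meta)) {
    stop_hifsort("counts has %d cells but cell_meta %d rows", ncol(counts),
                 nrow(cell_meta))
  }
  if (is.null(gene_meta)) {
    gid <- rownames(counts) %||% paste0("g", seq_len(nrow(counts)))
    gene_meta <- tibble::tibble(gene_id = gid)
  }
  gene_meta <- tibble::as_tibble(gene_meta)
  assert_columns(gene_meta, "gene_id", "gene_meta")
  if (nrow(gene_meta) != nrow(counts)) {
    stop_hifsort("counts has %d genes but gene_meta %d rows", nrow(counts),
                 nrow(gene_meta))
  }
  if (!"mito_flag" %in% names(gene_meta)) {
    pat <- paste0("^(", paste(mito_prefix, collapse = "|"), ")")
    gene_meta$mito_flag <- grepl(pat, gene_meta$gene_id)
  }
  dimnames(counts) <- list(gene_meta$gene_id, cell_meta$cell_id)
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  genotypes: %s\n",
              paste(sort(unique(x$cell_meta$genotype)), collapse = ", ")))
  cat(sprintf("  mice: %d; timepoints: %s\n", length(unique(x$cell_meta$mouse)),
              paste(sort(unique(x$cell_meta$timepoint)), collapse = ", ")))
  if ("identity" %in% names(x$cell_meta)) {
    cat(sprintf("  identities: %s\n",
                paste(sort(unique(x$cell_meta$identity)), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

# Subset cells by logical/integer index, keeping metadata aligned.
subset_cells <- function(m, idx) {
  m$counts <- m$counts[, idx, drop = FALSE]
  m$cell_meta <- m$cell_meta[idx, , drop = FALSE]
  m
}

#' Read a cell matrix from MatrixMarket + TSV sidecars
#'
#' Reads the standard triplet export: a MatrixMarket `.mtx` of genes x cells,
#' a gene table TSV (first column gene ids, optional `mito_flag`), and a cell
#' metadata TSV (must include `cell_id`, `mouse`, `sex`, `genotype`,
#' `timepoint`).
#'
#' @param mtx_path,genes_path,meta_path File paths.
#' @inheritParams cell_matrix
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(mtx_path, genes_path, meta_path,
                             mito_prefix = "mt-") {
  for (p in c(mtx_path, genes_path, meta_path)) {
    if (!file.exists(p)) stop_hifsort("file not found: %s", p)
  }
  counts <- Matrix::readMM(mtx_path)
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE)
  if (!"gene_id" %in% names(genes)) names(genes)[1] <- "gene_id"
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "?", cell_id = "c",
                                                  mouse = "c"))
  if (nrow(genes) != nrow(counts)) {
    stop_hifsort("gene table has %d rows but matrix %d genes", nrow(genes),
                 nrow(counts))
  }
  if (nrow(meta) != ncol(counts)) {
    stop_hifsort("cell metadata has %d rows but matrix %d cells", nrow(meta),
                 ncol(counts))
  }
  cell_matrix(counts, meta, genes, mito_prefix = mito_prefix)
}

#' Write a cell matrix as MatrixMarket + TSV sidecars
#'
#' Lossless counterpart of [read_cell_matrix()].
#'
#' @param m A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_cell_matrix <- function(m, dir, prefix = "matrix") {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(m$counts, paths[1])
  readr::write_tsv(m$gene_meta, paths[2])
  readr::write_tsv(m$cell_meta, paths[3])
  invisible(paths)
}
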