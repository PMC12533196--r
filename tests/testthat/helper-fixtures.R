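# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete simulation: 5 genotypes x 2 mice, late only, two
# identities, reduced gene space. Used by unit tests that need real(istic)
# data without end-to-end cost.
small_sim <- function() {
  cached("small_sim", function() {
    cfg <- sim_config(n_mice_per_genotype = 2, timepoints = "late",
                      cells_per_mouse = 120,
                      identities = default_identities()[1:2, ],
                      genes_total = 700, seed = 42)
    simulate_counts(cfg)
  })
}

# The full-scale synthetic fixture for end-to-end recovery: 5 genotypes x
# 4 mice x 200 cells/identity across two identities, planted |L2FC| = 2
# with 40 genes per isoform category.
recovery_fixture <- function() {
  cached("recovery_fixture", function() {
    cfg <- sim_config(n_mice_per_genotype = 4, timepoints = "late",
                      cells_per_mouse = 400,
                      identities = default_identities()[1:2, ],
                      genes_total = 2000, seed = 7)
    sim <- simulate_counts(cfg)
    m <- sim$matrix
    m$cell_meta <- dplyr::rename(m$cell_meta, true_identity = "identity")
    m <- apply_qc(m)
    m <- suppressWarnings(annotate_cells(m, sim$markers, sim$module_a,
                                         max_rank = 1500, n_bins = 20,
                                         n_ctrl = 20, seed = 11))
    des <- lapply(c("PT_S1_A", "PT_S1_B"), function(id) {
      pb <- aggregate_pseudobulk(m, id)
      list(vko_con = fit_de(pb, c("genotype", "VKO", "ConKO")),
           vhko = fit_de(pb, c("genotype", "VHKO", "VKO")),
           veko = fit_de(pb, c("genotype", "VEKO", "VKO")),
           vheko = fit_de(pb, c("genotype", "VHEKO", "VKO")))
    })
    names(des) <- c("PT_S1_A", "PT_S1_B")
    calls <- dplyr::bind_rows(lapply(des, function(d) {
      classify_dependence(d$vko_con, d$vhko, d$veko, d$vheko)
    }))
    list(sim = sim, matrix = m, des = des, calls = calls)
  })
}

# Hand-built tiny cell_matrix for contract tests.
toy_matrix <- function(counts = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3),
                       sex = rep("M", ncol(counts)),
                       mouse = paste0("m", seq_len(ncol(counts)))) {
  g <- paste0("g", seq_len(nrow(counts)))
  cells <- paste0("c", seq_len(ncol(counts)))
  dimnames(counts) <- list(g, cells)
  cell_matrix(counts,
              tibble::tibble(cell_id = cells, mouse = mouse, sex = sex,
                             genotype = "VKO", timepoint = "late"),
              tibble::tibble(gene_id = g, mito_flag = FALSE))
}

# A de_result-shaped tibble for driving the classifier directly.
fake_de <- function(genes, l2fc, padj, identity = "PT_S1_A",
                    contrast = "x_vs_y") {
  structure(tibble::tibble(gene = genes, base_mean = 100, l2fc = l2fc,
                           se = 0.1, stat = l2fc / 0.1, p = padj, padj = padj,
                           flag = ""),
            class = c("de_result", class(tibble::tibble())),
            contrast = contrast, identity = identity)
}

# Brute-force all-pairs neighbor counting oracle.
brute_neighbors <- function(x, y, r) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    sum(sqrt((x - x[i])^2 + (y - y[i])^2) <= r) - 1L
  }, numeric(1))
}
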