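# Marker derivation, rank-ceiling scores, type/class assignment.

test_that("marker derivation applies the three strict thresholds", {
  ref <- tibble::tibble(
    gene = paste0("g", 1:5),
    l2fc = c(1.5, 1.5, 1.0, 2.0, 0.5),
    pct_in = c(0.6, 0.5, 0.8, 0.9, 0.9),
    pct_out = c(0.1, 0.1, 0.1, 0.2, 0.05))
  out <- derive_markers(ref)
  # g1 passes; g2 fails pct_in (exactly 0.5, strict); g3 fails l2fc (exactly
  # 1.0); g4 fails pct_out (exactly 0.2); g5 fails l2fc
  expect_equal(out$gene, "g1")
  expect_warning(derive_markers(ref[5, , drop = FALSE]), "no genes")
})

test_that("rank-ceiling score equals the clipped-rank formula on a hand toy", {
  # 20 genes, 1 cell; expression puts signature genes at ranks 2, 5, 12
  expr <- matrix(0L, nrow = 20, ncol = 1)
  expr[, 1] <- 20:1          # gene i has rank i
  m <- toy_matrix(expr)
  sig <- c("g2", "g5", "g12")
  max_rank <- 10
  sc <- rank_signature_score(m, tibble::tibble(set = "s", gene = sig),
                             max_rank = max_rank)
  r <- pmin(c(2, 5, 12), max_rank + 1)
  n <- 3
  expected <- 1 - (sum(r) - n * (n + 1) / 2) / (n * max_rank)
  expect_equal(sc$s, expected)
})

test_that("rank-ceiling score attains its extremes", {
  expr <- matrix(0L, nrow = 30, ncol = 2)
  expr[1:3, 1] <- c(9L, 8L, 7L)   # signature occupies the top 3 ranks
  expr[25:27, 2] <- c(5L, 4L, 3L) # signature unexpressed in cell 1 sense
  m <- toy_matrix(expr)
  sc <- rank_signature_score(m, tibble::tibble(set = "s", gene = paste0("g", 1:3)),
                             max_rank = 10)
  expect_equal(sc$s[1], 1)
  # cell 2: signature genes all zero -> ranks clipped; score at the floor
  expect_lt(sc$s[2], (3 - 1) / (2 * 10) + 1e-9)
  expect_gte(sc$s[2], 0)
})

test_that("rank score is invariant to monotone transforms of expression", {
  sim <- small_sim()
  m <- subset_cells(sim$matrix, seq_len(50))
  mk <- sim$markers
  a <- rank_signature_score(m, mk, max_rank = 400)
  m2 <- m
  m2$counts <- m$counts * 7     # positive scaling
  b <- rank_signature_score(m2, mk, max_rank = 400)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("signature size contracts are enforced", {
  m <- toy_matrix(matrix(1:60, nrow = 20))
  expect_error(rank_signature_score(m, tibble::tibble(set = "s", gene = character())),
               "no marker genes")
  big <- tibble::tibble(set = "s", gene = paste0("g", 1:15))
  expect_error(rank_signature_score(m, big, max_rank = 10), "larger than max_rank")
  expect_error(rank_signature_score(m, tibble::tibble(set = "s", gene = "g1"),
                                    max_rank = 20), "max_rank must be")
})

test_that("argmax assignment and lexicographic tie-breaking", {
  sc <- structure(tibble::tibble(cell_id = c("c1", "c2"),
                                 PT_S1 = c(0.8, 0.5), PT_S2 = c(0.3, 0.5)),
                  class = c("score_table", class(tibble::tibble())))
  out <- assign_cell_type(sc)
  expect_equal(out$identity, c("PT_S1", "PT_S1"))
  expect_equal(out$tie, c(FALSE, TRUE))
})

test_that("cell types are recovered from planted identity blocks", {
  sim <- small_sim()
  m <- sim$matrix
  sc <- rank_signature_score(m, sim$markers, max_rank = 500)
  out <- assign_cell_type(sc)
  truth <- sub("_[AB]$", "", m$cell_meta$identity)
  expect_gte(mean(out$identity == truth), 0.95)
})

test_that("binned-control score matches a hand computation with logged controls", {
  # 6 genes, 2 bins, one control per signature gene, fixed seed
  set.seed(2)
  counts <- matrix(rpois(6 * 8, lambda = rep(c(20, 18, 16, 2, 2, 1), 8)),
                   nrow = 6)
  m <- toy_matrix(counts)
  sc <- binned_control_score(m, c("g1", "g5"), n_bins = 2, n_ctrl = 1, seed = 9)
  ctrl <- attr(sc, "controls")
  dat <- log1p(sweep(as.matrix(counts), 2, colSums(counts), "/") * 1e4)
  rownames(dat) <- paste0("g", 1:6)
  expected <- colMeans(dat[c("g1", "g5"), ]) - colMeans(dat[ctrl, , drop = FALSE])
  expect_equal(sc$score, unname(expected))
})

test_that("a signature drawn from its own control pool scores ~0", {
  set.seed(3)
  counts <- matrix(rpois(40 * 30, 10), nrow = 40)
  m <- toy_matrix(counts)
  sc <- suppressWarnings(binned_control_score(m, paste0("g", 1:20),
                                              n_bins = 1, n_ctrl = 40, seed = 1))
  expect_lt(max(abs(sc$score)), 0.2)
})

test_that("random signatures have near-zero expected binned-control score", {
  sim <- small_sim()
  m <- subset_cells(sim$matrix, seq_len(200))
  set.seed(4)
  means <- vapply(1:50, function(i) {
    gs <- sample(m$gene_meta$gene_id, 15)
    mean(suppressWarnings(binned_control_score(m, gs, n_bins = 20, n_ctrl = 10,
                                               seed = i))$score)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 0.01)
})

test_that("planted up-program scores separate VKO from ConKO cells", {
  sim <- small_sim()
  m <- sim$matrix
  up <- sim$truth$gene_id[sim$truth$direction == "up" &
                            sim$truth$isoform_truth == "HIF_independent"]
  sc <- suppressWarnings(binned_control_score(m, up, n_bins = 20, n_ctrl = 20,
                                              seed = 2))
  med <- tapply(sc$score, m$cell_meta$genotype, median)
  expect_gt(med[["VKO"]], med[["ConKO"]])
})

test_that("PT class threshold is strict and recovery is high", {
  sc <- structure(tibble::tibble(cell_id = c("a", "b", "c"),
                                 score = c(0.2, 0.125, 0.1)),
                  class = c("score_table", class(tibble::tibble())))
  expect_equal(assign_pt_class(sc)$class, c("A", "B", "B"))

  sim <- small_sim()
  m <- sim$matrix
  sa <- suppressWarnings(binned_control_score(m, sim$module_a, n_bins = 20,
                                              n_ctrl = 20, seed = 5))
  cls <- assign_pt_class(sa)
  truth <- sub("^.*_", "", m$cell_meta$identity)
  expect_gte(mean(cls$class == truth), 0.95)

  # an all-zero matrix scores 0 everywhere -> all Class B
  z <- toy_matrix(matrix(0L, nrow = 10, ncol = 4))
  sz <- suppressWarnings(binned_control_score(z, c("g1", "g2"), n_bins = 1,
                                              n_ctrl = 2, seed = 1))
  expect_true(all(assign_pt_class(sz)$class == "B"))
})

test_that("sex-specific marker sets score the sex-matched gene list", {
  sim <- small_sim()
  m <- subset_cells(sim$matrix, seq_len(400))
  m <- suppressWarnings(annotate_cells(m, sim$markers, sim$module_a,
                                       max_rank = 500, n_bins = 20,
                                       n_ctrl = 20, seed = 1))
  truth <- small_sim()$matrix$cell_meta$identity[seq_len(400)]
  expect_gte(mean(m$cell_meta$identity == truth), 0.9)
})
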