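# The isoform-dependence decision ledger.

# Independent brute-force rule evaluator, written directly from the decision
# rules without reference to the package implementation. Operates on one
# gene's scalar contrast summaries.
brute_category <- function(l2fc_v, padj_v, l2fc_h, padj_h, l2fc_e, padj_e,
                           l2fc_he, padj_he, l2fc_min = 1, alpha = 0.05) {
  vhl_dep <- abs(l2fc_v) > l2fc_min && padj_v < alpha
  if (!vhl_dep) return(NA_character_)
  dep <- function(l2fc_x, padj_x) {
    padj_x < alpha &&
      ((l2fc_v > 0 && l2fc_x < 0) || (l2fc_v < 0 && l2fc_x > 0)) &&
      abs(l2fc_x) > abs(l2fc_v) / 2
  }
  h1 <- dep(l2fc_h, padj_h)
  h2 <- dep(l2fc_e, padj_e)
  he <- dep(l2fc_he, padj_he)
  if (h1 && h2) return("HIF1A_or_HIF2A")
  if (h1) return("HIF1A_alone")
  if (h2) return("HIF2A_alone")
  if (he) return("HIF1A_plus_HIF2A")
  "ambiguous"
}

test_that("the worked single-gene example lands in HIF1A_alone", {
  g <- "gX"
  calls <- classify_dependence(
    fake_de(g, 2.0, 0.001), fake_de(g, -1.2, 0.01),
    fake_de(g, -0.3, 0.4), fake_de(g, -1.8, 0.001))
  expect_equal(calls$category, "HIF1A_alone")
  expect_true(calls$hif1a_dependent)
  expect_false(calls$epas1_dependent)
  expect_true(calls$hif1a_epas1_dependent)
})

test_that("the half-magnitude rule is strict", {
  g <- "gX"
  # |−0.9| is not more than half of |2.0| -> hif1a flag stays FALSE
  calls <- classify_dependence(
    fake_de(g, 2.0, 0.001), fake_de(g, -0.9, 0.001),
    fake_de(g, 0.0, 0.9), fake_de(g, -1.8, 0.001))
  expect_false(calls$hif1a_dependent)
  expect_equal(calls$category, "HIF1A_plus_HIF2A")
  # exactly half (−1.0 vs 2.0) is still not "more than half"
  calls2 <- classify_dependence(
    fake_de(g, 2.0, 0.001), fake_de(g, -1.0, 0.001),
    fake_de(g, 0.0, 0.9), fake_de(g, -1.8, 0.001))
  expect_false(calls2$hif1a_dependent)
})

test_that("a knockout effect in the same direction never counts as dependence", {
  g <- "gX"
  calls <- classify_dependence(
    fake_de(g, 2.0, 0.001), fake_de(g, 1.6, 0.001),
    fake_de(g, -1.6, 0.001), fake_de(g, 1.8, 0.001))
  expect_false(calls$hif1a_dependent)
  expect_true(calls$epas1_dependent)
  expect_equal(calls$category, "HIF2A_alone")
})

test_that("classifier matches the brute-force evaluator on an exhaustive grid", {
  # VKO effect: up or down; each knockout contrast: significant+large,
  # significant+small, or non-significant, crossed with opposite/same sign
  states <- tidyr::expand_grid(
    v_sign = c(1, -1),
    h = 1:6, e = 1:6, he = 1:6
  )
  state_l2fc <- function(code, v_sign) {
    # codes 1..6: (sig, big, opp), (sig, small, opp), (nonsig, big, opp),
    #             (sig, big, same), (sig, small, same), (nonsig, big, same)
    big <- 1.6; small <- 0.8
    mag <- c(big, small, big, big, small, big)[code]
    sgn <- c(-1, -1, -1, 1, 1, 1)[code] * v_sign
    padj <- c(0.01, 0.01, 0.5, 0.01, 0.01, 0.5)[code]
    c(l2fc = mag * sgn, padj = padj)
  }
  genes <- sprintf("g%03d", seq_len(nrow(states)))
  v <- h <- e <- he <- list()
  expected <- character(nrow(states))
  for (i in seq_len(nrow(states))) {
    vs <- states$v_sign[i]
    hv <- state_l2fc(states$h[i], vs)
    ev <- state_l2fc(states$e[i], vs)
    hev <- state_l2fc(states$he[i], vs)
    v[[i]] <- c(l2fc = 2 * vs, padj = 0.001)
    h[[i]] <- hv; e[[i]] <- ev; he[[i]] <- hev
    expected[i] <- brute_category(2 * vs, 0.001, hv["l2fc"], hv["padj"],
                                  ev["l2fc"], ev["padj"],
                                  hev["l2fc"], hev["padj"])
  }
  mk <- function(lst) fake_de(genes, vapply(lst, `[[`, 0, "l2fc"),
                              vapply(lst, `[[`, 0, "padj"))
  calls <- classify_dependence(mk(v), mk(h), mk(e), mk(he))
  got <- calls$category[match(genes, calls$gene)]
  expect_equal(got, expected)
})

test_that("the category function is total over the dependence-flag lattice", {
  flags <- tidyr::expand_grid(h1 = c(TRUE, FALSE), h2 = c(TRUE, FALSE),
                              he = c(TRUE, FALSE))
  cat_of <- function(h1, h2, he) {
    if (h1 && h2) "HIF1A_or_HIF2A"
    else if (h1) "HIF1A_alone"
    else if (h2) "HIF2A_alone"
    else if (he) "HIF1A_plus_HIF2A"
    else "ambiguous"
  }
  # realize each flag combination with concrete contrasts and check totality
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    mk1 <- function(on) if (on) fake_de("g", -1.5, 0.01) else fake_de("g", -0.2, 0.9)
    calls <- classify_dependence(fake_de("g", 2, 0.001), mk1(f$h1), mk1(f$h2),
                                 mk1(f$he))
    expect_equal(calls$category, cat_of(f$h1, f$h2, f$he))
  }
})

test_that("temporal classes follow the definitional rules", {
  genes <- c("ge", "ga", "gboth", "gshared", "gnone")
  # early contrast: ge and gboth regulated
  de_early <- fake_de(genes, c(2, 0.2, 1.8, 0.1, 0.2),
                      c(0.01, 0.9, 0.01, 0.9, 0.9))
  # VKO late vs early: ga, gboth, gshared regulated
  de_vko_t <- fake_de(genes, c(0.1, 1.7, 1.6, 1.5, 0.1),
                      c(0.9, 0.01, 0.01, 0.01, 0.9))
  # ConKO late vs early: gshared regulated (time effect not Vhl-specific)
  de_con_t <- fake_de(genes, c(0.1, 0.1, 0.1, 1.4, 0.1),
                      c(0.9, 0.9, 0.9, 0.01, 0.9))
  out <- classify_temporal(de_early, de_vko_t, de_con_t)
  expect_equal(out$temporal[out$gene == "ge"], "early")
  expect_equal(out$temporal[out$gene == "ga"], "adaptive")
  expect_equal(out$temporal[out$gene == "gboth"], "both_excluded")
  expect_false("gshared" %in% out$gene)
  expect_false("gnone" %in% out$gene)
})

test_that("pooling takes unions and excludes cross-isoform conflicts", {
  calls <- dplyr::bind_rows(
    classify_dependence(fake_de("g1", 2, 0.001, identity = "PT_S1_A"),
                        fake_de("g1", -1.5, 0.01), fake_de("g1", -0.1, 0.9),
                        fake_de("g1", -1.8, 0.01)),
    classify_dependence(fake_de("g1", 2, 0.001, identity = "PT_S3_B"),
                        fake_de("g1", -0.1, 0.9), fake_de("g1", -1.5, 0.01),
                        fake_de("g1", -1.8, 0.01)),
    classify_dependence(fake_de("g2", -2, 0.001, identity = "PT_S1_A"),
                        fake_de("g2", 1.5, 0.01), fake_de("g2", 0.1, 0.9),
                        fake_de("g2", 1.8, 0.01))
  )
  pooled <- pool_categories(calls)
  # g1 is HIF1A_alone in S1_A and HIF2A_alone in S3_B -> conflict, excluded
  expect_equal(pooled$conflicts$gene, "g1")
  expect_false("g1" %in% pooled$hif1a$gene)
  expect_false("g1" %in% pooled$hif2a$gene)
  expect_true("g2" %in% pooled$hif1a$gene)
  expect_equal(length(intersect(pooled$hif1a$gene, pooled$hif2a$gene)), 0)
})

test_that("anticorrelation diagnostic: exact reversal gives rho = -1", {
  genes <- paste0("g", 1:30)
  l2fc <- seq(-3, 3, length.out = 30)
  a <- fake_de(genes, l2fc, 0.01)
  b <- fake_de(genes, -l2fc, 0.01)
  expect_equal(anticorrelation_diagnostic(b, a, genes)$rho, -1)
})

test_that("independent random l2fc vectors rarely exceed |rho| 0.2", {
  set.seed(6)
  hits <- vapply(1:40, function(i) {
    genes <- paste0("g", 1:200)
    a <- fake_de(genes, rnorm(200), 0.5)
    b <- fake_de(genes, rnorm(200), 0.5)
    abs(anticorrelation_diagnostic(b, a, genes)$rho) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("missing contrasts and tiny subsets are rejected", {
  expect_error(classify_dependence(fake_de("g", 2, 0.01), NULL,
                                   fake_de("g", 0, 1), fake_de("g", 0, 1)),
               "required")
  expect_error(anticorrelation_diagnostic(fake_de("g", 1, 0.1),
                                          fake_de("g", 1, 0.1), "g"),
               ">= 10")
})

test_that("planted temporal programs are recovered from timepoint contrasts", {
  pp <- list(
    planted_program(sprintf("g%04d", 401:420), "up", 2, "HIF_independent", "early"),
    planted_program(sprintf("g%04d", 421:440), "up", 2, "HIF_independent", "adaptive"),
    planted_program(sprintf("g%04d", 441:460), "down", 2, "HIF_independent", "adaptive"))
  cfg <- sim_config(n_mice_per_genotype = 4, genotypes = c("ConKO", "VKO"),
                    timepoints = c("early", "late"), cells_per_mouse = 100,
                    identities = default_identities()[1, ],
                    genes_total = 600, planted_programs = pp, seed = 19)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  sub <- function(cond) subset_cells(m, cond)
  de_early <- fit_de(aggregate_pseudobulk(sub(m$cell_meta$timepoint == "early"),
                                          "PT_S1_A"),
                     c("genotype", "VKO", "ConKO"))
  de_vko <- fit_de(aggregate_pseudobulk(sub(m$cell_meta$genotype == "VKO"),
                                        "PT_S1_A"),
                   c("timepoint", "late", "early"))
  de_con <- fit_de(aggregate_pseudobulk(sub(m$cell_meta$genotype == "ConKO"),
                                        "PT_S1_A"),
                   c("timepoint", "late", "early"))
  out <- classify_temporal(de_early, de_vko, de_con)
  truth <- sim$truth
  adaptive_truth <- truth$gene_id[truth$timing == "adaptive"]
  early_truth <- truth$gene_id[truth$timing == "early"]
  called_adaptive <- out$gene[out$temporal == "adaptive"]
  called_early <- out$gene[out$temporal == "early"]
  expect_gte(mean(adaptive_truth %in% called_adaptive), 0.8)
  expect_lte(mean(early_truth %in% called_adaptive), 0.05)
  expect_gte(mean(early_truth %in% called_early), 0.8)
})
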