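# The generator is first-class: every downstream stage is tested against
# its planted truth, so its own distributional claims are verified here.

test_that("identical config and seed give bit-identical matrices", {
  cfg <- sim_config(n_mice_per_genotype = 2, timepoints = "late",
                    cells_per_mouse = 100,
                    identities = default_identities()[1, ],
                    genes_total = 600, seed = 5)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$matrix$cell_meta, b$matrix$cell_meta)
  expect_identical(a$truth, b$truth)
})

test_that("planted gene sets must be disjoint within a direction", {
  pp <- list(planted_program(c("g0401", "g0402"), "up", 2, "HIF1A_alone", "early"),
             planted_program(c("g0402", "g0403"), "up", 2, "HIF2A_alone", "early"))
  expect_error(sim_config(planted_programs = pp), "overlap")
  # same genes in opposite directions is allowed
  pp2 <- list(planted_program(c("g0401"), "up", 2, "HIF1A_alone", "early"),
              planted_program(c("g0401"), "down", 2, "HIF2A_alone", "early"))
  expect_s3_class(sim_config(planted_programs = pp2), "sim_config")
})

test_that("planted truth is complete: one category per gene per direction", {
  sim <- small_sim()
  planted <- unlist(lapply(sim$config$planted_programs, `[[`, "gene_ids"))
  expect_setequal(sim$truth$gene_id, planted)
  per_dir <- dplyr::count(sim$truth, gene_id, direction)
  expect_true(all(per_dir$n == 1))
})

test_that("negative-binomial marginals: method-of-moments dispersion within 15%", {
  set.seed(1)
  cfg <- sim_config(n_mice_per_genotype = 1, genotypes = "ConKO",
                    timepoints = "late", cells_per_mouse = 10000,
                    identities = default_identities()[1, ],
                    genes_total = 600, planted_programs = list(),
                    nb_dispersion = 0.4, library_size_lognorm = c(meanlog = 0, sdlog = 0),
                    mouse_random_effect_sd = 0, seed = 21)
  sim <- simulate_counts(cfg)
  cnt <- as.matrix(sim$matrix$counts)
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  keep <- mu > 2  # moment estimate unstable for rare genes
  alpha_hat <- (v[keep] - mu[keep]) / mu[keep]^2
  expect_lt(abs(median(alpha_hat) - 0.4) / 0.4, 0.15)
})

test_that("planted up effect of L2FC 2 gives a ~4-fold empirical mean ratio", {
  pp <- list(planted_program(sprintf("g%04d", 401:410), "up", 2,
                             "HIF_independent", "early"))
  cfg <- sim_config(n_mice_per_genotype = 4, genotypes = c("ConKO", "VKO"),
                    timepoints = "late", cells_per_mouse = 200,
                    identities = default_identities()[1, ],
                    genes_total = 600, planted_programs = pp,
                    mouse_random_effect_sd = 0, seed = 9)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  vko <- Matrix::rowMeans(m$counts[, m$cell_meta$genotype == "VKO"])
  con <- Matrix::rowMeans(m$counts[, m$cell_meta$genotype == "ConKO"])
  ratio <- mean(vko[sprintf("g%04d", 401:410)]) / mean(con[sprintf("g%04d", 401:410)])
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1)
})

test_that("isoform truth controls which genotypes carry the effect", {
  pp <- list(planted_program(sprintf("g%04d", 401:410), "up", 2,
                             "HIF1A_alone", "early"))
  cfg <- sim_config(n_mice_per_genotype = 2, timepoints = "late",
                    cells_per_mouse = 150,
                    identities = default_identities()[1, ],
                    genes_total = 600, planted_programs = pp,
                    mouse_random_effect_sd = 0.05, seed = 13)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  gmeans <- sapply(c("ConKO", "VKO", "VHKO", "VEKO", "VHEKO"), function(g) {
    mean(Matrix::rowMeans(m$counts[sprintf("g%04d", 401:410),
                                   m$cell_meta$genotype == g, drop = FALSE]))
  })
  # effect requires HIF1A: present in VKO and VEKO, absent in VHKO/VHEKO
  expect_gt(gmeans["VKO"] / gmeans["ConKO"], 2.5)
  expect_gt(gmeans["VEKO"] / gmeans["ConKO"], 2.5)
  expect_lt(gmeans["VHKO"] / gmeans["ConKO"], 1.5)
  expect_lt(gmeans["VHEKO"] / gmeans["ConKO"], 1.5)
})

test_that("adaptive programs act only at the late timepoint", {
  pp <- list(planted_program(sprintf("g%04d", 401:410), "up", 2,
                             "HIF_independent", "adaptive"))
  cfg <- sim_config(n_mice_per_genotype = 2, genotypes = c("ConKO", "VKO"),
                    timepoints = c("early", "late"), cells_per_mouse = 150,
                    identities = default_identities()[1, ],
                    genes_total = 600, planted_programs = pp,
                    mouse_random_effect_sd = 0.05, seed = 17)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  mn <- function(g, tp) {
    sel <- m$cell_meta$genotype == g & m$cell_meta$timepoint == tp
    mean(Matrix::rowMeans(m$counts[sprintf("g%04d", 401:410), sel, drop = FALSE]))
  }
  expect_lt(mn("VKO", "early") / mn("ConKO", "early"), 1.5)
  expect_gt(mn("VKO", "late") / mn("ConKO", "late"), 2.5)
})

test_that("spatial generator is deterministic and obeys boundary dynamics", {
  cfg <- spatial_sim_config(n_cells = 400, seed = 3)
  a <- simulate_spatial(cfg, genotype = "VKO", timepoint = "late")
  b <- simulate_spatial(cfg, genotype = "VKO", timepoint = "late")
  expect_identical(a$cells, b$cells)

  # no dynamics: tagged fraction matches tag_fraction within binomial CI
  cfg0 <- spatial_sim_config(n_cells = 1500, tag_fraction = 0.3,
                             clone_expansion_rate = 0,
                             elimination_fraction = 0, seed = 5)
  r0 <- simulate_spatial(cfg0, genotype = "VKO", timepoint = "late")
  frac <- mean(r0$truth$tagged)
  ci <- 3 * sqrt(0.3 * 0.7 / 1500)
  expect_lt(abs(frac - 0.3), ci)
  expect_equal(nrow(r0$truth$parent_map), 0)

  # total elimination: no tagged cells left (papilla, late)
  cfg1 <- spatial_sim_config(region = "papilla", n_cells = 400,
                             elimination_fraction = 1, seed = 6)
  r1 <- simulate_spatial(cfg1, genotype = "VKO", timepoint = "late")
  expect_equal(sum(r1$truth$tagged), 0)
})

test_that("founders respect the minimum spacing and field bounds", {
  cfg <- spatial_sim_config(n_cells = 300, clone_expansion_rate = 0,
                            field_size_um = c(400, 400), seed = 8)
  r <- simulate_spatial(cfg, genotype = "ConKO", timepoint = "early")
  d <- as.matrix(dist(cbind(r$cells$x_um, r$cells$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_spacing_um)
  expect_true(all(r$cells$x_um >= 0 & r$cells$x_um <= 400))
  expect_error(simulate_spatial(spatial_sim_config(n_cells = 5000,
                                                   field_size_um = c(100, 100),
                                                   seed = 1)),
               "too small")
})

test_that("clonal expansion raises tagged-neighbor counts over static fields", {
  mk <- function(rate, seed) {
    cfg <- spatial_sim_config(n_cells = 800, clone_expansion_rate = rate,
                              elimination_fraction = 0, seed = seed)
    r <- simulate_spatial(cfg, genotype = "VKO", timepoint = "late")
    cells <- r$cells
    cells$tagged <- r$truth$tagged
    tg <- cells[cells$tagged, ]
    mean(brute_neighbors(tg$x_um, tg$y_um, 16))
  }
  expanded <- mk(1, 31)
  static <- mk(0, 31)
  expect_gt(expanded, static)
})
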