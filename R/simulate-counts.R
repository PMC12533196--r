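# Synthetic single-cell counts with planted, fully known ground truth.
#
# The generator emulates the study design this package analyzes: five
# genotypes (ConKO control, VKO Vhl-null, VHKO +Hif1a-null, VEKO +Epas1-null,
# VHEKO both), 4 mice per genotype per timepoint cohort, proximal-tubule
# identities PT S1/S2/S3 crossed with a Class A/B expression dichotomy,
# sex-dimorphic genes, a per-mouse random effect motivating pseudo-bulking,
# and planted gene programs whose HIF isoform dependence and early/adaptive
# timing are known exactly.

#' Default PT identities
#'
#' The six strata used throughout: PT S1/S2/S3 crossed with Class A/B.
#' @return Tibble with `cell_type` and `class`.
#' @export
default_identities <- function() {
  tidyr::expand_grid(cell_type = c("PT_S1", "PT_S2", "PT_S3"),
                     class = c("A", "B")) |>
    dplyr::mutate(identity = paste(.data$cell_type, .data$class, sep = "_"))
}

# Which Vhl-null genotypes still express a planted effect, given which HIF
# isoform(s) the effect requires. Deleting a required isoform removes the
# effect; redundant isoforms ("plus") require deleting both.
isoform_effect_genotypes <- function(isoform_truth) {
  switch(isoform_truth,
    HIF1A_alone      = c("VKO", "VEKO"),
    HIF2A_alone      = c("VKO", "VHKO"),
    HIF1A_or_HIF2A   = "VKO",
    HIF1A_plus_HIF2A = c("VKO", "VHKO", "VEKO"),
    HIF_independent  = c("VKO", "VHKO", "VEKO", "VHEKO"),
    stop_hifsort("unknown isoform_truth: %s", isoform_truth)
  )
}

#' Define a planted gene program
#'
#' @param gene_ids Genes carrying the effect (disjoint across programs within
#'   a direction).
#' @param direction `"up"` or `"down"` (in VKO vs ConKO).
#' @param base_l2fc Magnitude of the log2 fold change in VKO vs ConKO.
#' @param isoform_truth One of `"HIF1A_alone"`, `"HIF2A_alone"`,
#'   `"HIF1A_or_HIF2A"`, `"HIF1A_plus_HIF2A"`, `"HIF_independent"`.
#' @param timing `"early"` (present from the early timepoint onwards) or
#'   `"adaptive"` (present only late).
#' @param identity_scope Identities in which the program acts (default all).
#' @return A list of class `planted_program`.
#' @export
planted_program <- function(gene_ids, direction = c("up", "down"),
                            base_l2fc = 2,
                            isoform_truth = "HIF1A_alone",
                            timing = c("early", "adaptive"),
                            identity_scope = NULL) {
  direction <- match.arg(direction)
  timing <- match.arg(timing)
  isoform_effect_genotypes(isoform_truth)  # validates
  structure(list(gene_ids = gene_ids, direction = direction,
                 base_l2fc = base_l2fc, isoform_truth = isoform_truth,
                 timing = timing, identity_scope = identity_scope),
            class = "planted_program")
}

# Default planted programs: for every isoform category, genes in both
# directions and both timings, |L2FC| = 2, 40 genes per category.
default_planted_programs <- function(genes_per_program = 10,
                                     base_l2fc = 2,
                                     first_gene_index = 401,
                                     gene_prefix = "g") {
  cats <- c("HIF1A_alone", "HIF2A_alone", "HIF1A_or_HIF2A",
            "HIF1A_plus_HIF2A", "HIF_independent")
  grid <- tidyr::expand_grid(isoform_truth = cats,
                             direction = c("up", "down"),
                             timing = c("early", "adaptive"))
  idx <- first_gene_index
  purrr::pmap(grid, function(isoform_truth, direction, timing) {
    ids <- sprintf("%s%04d", gene_prefix, idx:(idx + genes_per_program - 1))
    idx <<- idx + genes_per_program
    planted_program(ids, direction = direction, base_l2fc = base_l2fc,
                    isoform_truth = isoform_truth, timing = timing)
  })
}

#' Simulation configuration for synthetic single-cell counts
#'
#' Defaults mirror the study conditions: 4 mice per genotype per timepoint
#' cohort (sexes balanced), the five genotypes, six PT identities with 200
#' cells each per mouse, and planted programs of |L2FC| = 2 with 40 genes per
#' isoform category.
#'
#' @param n_mice_per_genotype Mice per genotype per timepoint (default 4).
#' @param genotypes Genotype labels; `"ConKO"` is the control.
#' @param timepoints Subset of `c("early", "late")`.
#' @param cells_per_mouse Cells per mouse, split evenly across identities
#'   (default 1200, i.e. 200 per identity).
#' @param genes_total Number of non-mitochondrial genes (default 2000); 10
#'   mitochondrial genes (`mt-*`) are appended.
#' @param identities Tibble as from [default_identities()].
#' @param planted_programs List of [planted_program()] objects.
#' @param nb_dispersion Gene-level negative-binomial dispersion alpha
#'   (Var = mu + alpha mu^2; default 0.4).
#' @param library_size_lognorm Named numeric `c(meanlog=, sdlog=)` for the
#'   per-cell library-size factor.
#' @param n_sex_genes,sex_l2fc Number of sex-dimorphic genes and their male
#'   vs female log2 effect.
#' @param mouse_random_effect_sd Log-scale SD of the per-mouse scalar on mu;
#'   creates the within-genotype correlation that motivates pseudo-bulking.
#' @param marker_l2fc Log2 elevation of cell-type marker genes in their own
#'   (sex-matched) cell type.
#' @param module_l2fc Log2 elevation of the Class A/B module blocks in their
#'   class.
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mice_per_genotype = 4,
                       genotypes = c("ConKO", "VKO", "VHKO", "VEKO", "VHEKO"),
                       timepoints = c("early", "late"),
                       cells_per_mouse = 1200,
                       genes_total = 2000,
                       identities = default_identities(),
                       planted_programs = default_planted_programs(),
                       nb_dispersion = 0.4,
                       library_size_lognorm = c(meanlog = 0, sdlog = 0.25),
                       n_sex_genes = 50, sex_l2fc = 1,
                       mouse_random_effect_sd = 0.15,
                       marker_l2fc = 3, module_l2fc = 2,
                       seed = 1L) {
  if (nb_dispersion <= 0) stop_hifsort("nb_dispersion must be > 0")
  n_id <- nrow(identities)
  if (floor(cells_per_mouse / n_id) < 50) {
    stop_hifsort("cells_per_mouse/identities must give >= 50 cells per identity")
  }
  for (dir in c("up", "down")) {
    ids <- unlist(lapply(planted_programs,
                         function(p) if (p$direction == dir) p$gene_ids))
    if (anyDuplicated(ids)) {
      stop_hifsort("planted gene sets overlap within direction '%s'", dir)
    }
  }
  structure(list(n_mice_per_genotype = n_mice_per_genotype,
                 genotypes = genotypes, timepoints = timepoints,
                 cells_per_mouse = cells_per_mouse, genes_total = genes_total,
                 identities = identities,
                 planted_programs = planted_programs,
                 nb_dispersion = nb_dispersion,
                 library_size_lognorm = library_size_lognorm,
                 n_sex_genes = n_sex_genes, sex_l2fc = sex_l2fc,
                 mouse_random_effect_sd = mouse_random_effect_sd,
                 marker_l2fc = marker_l2fc, module_l2fc = module_l2fc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fixed gene-block layout. Marker and module blocks occupy the head of the
# gene list; planted programs default to indices 401+.
sim_gene_layout <- function(config) {
  gid <- sprintf("g%04d", seq_len(config$genes_total))
  list(
    gene_ids = gid,
    markers = tibble::tibble(
      set = rep(c("PT_S1", "PT_S2", "PT_S2", "PT_S3", "PT_S3"),
                times = c(60, 30, 30, 30, 30)),
      sex = rep(c(NA, "M", "F", "M", "F"), times = c(60, 30, 30, 30, 30)),
      gene = gid[1:180]
    ),
    module_a = gid[181:260],
    module_b = gid[261:340],
    sex_genes = gid[341:(340 + config$n_sex_genes)]
  )
}

#' Simulate a synthetic single-cell count matrix with known truth
#'
#' Counts are negative-binomial draws around a multiplicative mean model:
#' per-gene log-normal baseline x cell-type/class marker elevation x sex
#' effect x per-mouse random effect x per-cell library factor x planted
#' genotype/timepoint effect. Ten mitochondrial genes (`mt-*`) are appended
#' so QC is exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (a [cell_matrix()] whose `cell_meta`
#'   includes the true `identity`), `truth` (tibble: one row per planted gene
#'   with direction, signed `l2fc`, `isoform_truth`, `timing`), `markers`
#'   (marker tibble: `set`, `sex`, `gene`), `module_a`, `module_b` (gene-id
#'   vectors), and `config`.
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- sim_gene_layout(config)
  G <- config$genes_total
  gid <- lay$gene_ids

  base <- rlnorm(G, meanlog = log(0.8), sdlog = 1)
  names(base) <- gid
  # keep marker/module blocks expressed at a solid baseline so elevation is
  # detectable over sampling noise
  structured <- c(lay$markers$gene, lay$module_a, lay$module_b,
                  unlist(lapply(config$planted_programs, `[[`, "gene_ids")))
  base[structured] <- pmax(base[structured], 0.5)

  mito_id <- sprintf("mt-g%02d", 1:10)
  mito_base <- rlnorm(10, meanlog = log(8), sdlog = 0.3)

  sex_mult_m <- setNames(rep(1, G), gid)
  sex_mult_m[lay$sex_genes] <- 2^config$sex_l2fc

  # identity x sex multiplier for markers and modules
  ident_mult <- function(identity_row, sex) {
    mult <- setNames(rep(1, G), gid)
    mk <- lay$markers
    own <- mk$gene[mk$set == identity_row$cell_type &
                     (is.na(mk$sex) | mk$sex == sex)]
    mult[own] <- 2^config$marker_l2fc
    if (identity_row$class == "A") {
      mult[lay$module_a] <- 2^config$module_l2fc
    } else {
      mult[lay$module_b] <- 2^config$module_l2fc
    }
    mult
  }

  planted_mult <- function(genotype, timepoint) {
    mult <- setNames(rep(1, G), gid)
    for (p in config$planted_programs) {
      if (!(genotype %in% isoform_effect_genotypes(p$isoform_truth))) next
      if (p$timing == "adaptive" && timepoint != "late") next
      l2fc <- if (p$direction == "up") p$base_l2fc else -p$base_l2fc
      mult[p$gene_ids] <- mult[p$gene_ids] * 2^l2fc
    }
    mult
  }

  n_id <- nrow(config$identities)
  cells_per_identity <- floor(config$cells_per_mouse / n_id)
  size <- 1 / config$nb_dispersion
  ml <- config$library_size_lognorm[["meanlog"]]
  sl <- config$library_size_lognorm[["sdlog"]]

  blocks <- list()
  meta <- list()
  bi <- 0L
  for (tp in config$timepoints) {
    for (geno in config$genotypes) {
      for (mi in seq_len(config$n_mice_per_genotype)) {
        mouse <- sprintf("%s_%s_m%d", geno, tp, mi)
        sex <- if (mi %% 2 == 1) "M" else "F"
        mouse_fac <- rlnorm(1, 0, config$mouse_random_effect_sd)
        pmult <- planted_mult(geno, tp)
        for (ii in seq_len(n_id)) {
          idr <- config$identities[ii, ]
          mu_g <- base * ident_mult(idr, sex) * pmult * mouse_fac
          if (sex == "M") mu_g <- mu_g * sex_mult_m
          lib <- rlnorm(cells_per_identity, ml, sl)
          mu <- outer(c(mu_g, mito_base * mouse_fac), lib)
          cnt <- matrix(rnbinom(length(mu), mu = mu, size = size),
                        nrow = nrow(mu))
          bi <- bi + 1L
          blocks[[bi]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                      "CsparseMatrix")
          meta[[bi]] <- tibble::tibble(
            cell_id = sprintf("%s_%s_c%03d", mouse, idr$identity,
                              seq_len(cells_per_identity)),
            mouse = mouse, sex = sex, genotype = geno, timepoint = tp,
            identity = idr$identity
          )
        }
      }
    }
  }
  counts <- do.call(cbind, blocks)
  cell_meta <- dplyr::bind_rows(meta)
  gene_meta <- tibble::tibble(gene_id = c(gid, mito_id),
                              mito_flag = c(rep(FALSE, G), rep(TRUE, 10)))
  rownames(counts) <- gene_meta$gene_id
  colnames(counts) <- cell_meta$cell_id
  m <- cell_matrix(counts, cell_meta, gene_meta)

  truth <- purrr::map_dfr(config$planted_programs, function(p) {
    tibble::tibble(gene_id = p$gene_ids, direction = p$direction,
                   l2fc = if (p$direction == "up") p$base_l2fc else -p$base_l2fc,
                   isoform_truth = p$isoform_truth, timing = p$timing)
  })

  list(matrix = m, truth = truth, markers = lay$markers,
       module_a = lay$module_a, module_b = lay$module_b, config = config)
}

#' Write a simulation to disk (MTX + TSV + YAML)
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_matrix(sim$matrix, dir, prefix = "sim")
  readr::write_tsv(sim$truth, file.path(dir, "sim_truth.tsv"))
  readr::write_tsv(sim$markers, file.path(dir, "sim_markers.tsv"))
  cfg <- sim$config
  cfg$identities <- as.list(cfg$identities)
  cfg$planted_programs <- lapply(cfg$planted_programs, unclass)
  yaml::write_yaml(lapply(unclass(cfg), unclass), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
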