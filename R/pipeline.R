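# Configuration-driven orchestration: qc -> annotate -> pseudobulk DE ->
# classify -> pool -> score, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it, so a run is a pure function of (inputs, config, seed).
#' @param outdir Output directory.
#' @param sim Named list of [sim_config()] overrides (the bundled synthetic
#'   fixture is used when no input paths are given).
#' @param qc Named list of [qc_params()] overrides.
#' @param annotate List: `max_rank`, `class_threshold`, `n_bins`, `n_ctrl`.
#' @param de List: `l2fc_min`, `alpha`, `min_cells`.
#' @param score List: `n_bins`, `n_ctrl`, `anchor_ref`, `anchor_target`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("hifsort_run_"),
                            sim = list(), qc = list(),
                            annotate = list(max_rank = 1500,
                                            class_threshold = 0.125,
                                            n_bins = 20, n_ctrl = 20),
                            de = list(l2fc_min = 1.0, alpha = 0.05,
                                      min_cells = 10),
                            score = list(n_bins = 20, n_ctrl = 20,
                                         anchor_ref = "ConKO",
                                         anchor_target = "VKO")) {
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 qc = qc, annotate = annotate, de = de, score = score),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_hifsort("config file not found: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Fit the standard contrast battery for one identity.
fit_identity_contrasts <- function(m, identity, de_cfg) {
  late <- subset_cells(m, m$cell_meta$timepoint == "late")
  pb <- aggregate_pseudobulk(late, identity, min_cells = de_cfg$min_cells)
  des <- list(
    vko_con = fit_de(pb, c("genotype", "VKO", "ConKO")),
    vhko_vko = fit_de(pb, c("genotype", "VHKO", "VKO")),
    veko_vko = fit_de(pb, c("genotype", "VEKO", "VKO")),
    vheko_vko = fit_de(pb, c("genotype", "VHEKO", "VKO"))
  )
  if ("early" %in% m$cell_meta$timepoint) {
    early <- subset_cells(m, m$cell_meta$timepoint == "early")
    pb_e <- aggregate_pseudobulk(early, identity, min_cells = de_cfg$min_cells)
    vko_cells <- subset_cells(m, m$cell_meta$genotype == "VKO")
    con_cells <- subset_cells(m, m$cell_meta$genotype == "ConKO")
    pb_vko <- aggregate_pseudobulk(vko_cells, identity,
                                   min_cells = de_cfg$min_cells)
    pb_con <- aggregate_pseudobulk(con_cells, identity,
                                   min_cells = de_cfg$min_cells)
    des$vko_con_early <- fit_de(pb_e, c("genotype", "VKO", "ConKO"))
    des$vko_late_early <- fit_de(pb_vko, c("timepoint", "late", "early"))
    des$con_late_early <- fit_de(pb_con, c("timepoint", "late", "early"))
  }
  des
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or read) counts, QC, annotate
#' (cell type by rank-ceiling score, PT class by binned-control Module A
#' score), pseudo-bulk DE per identity (late-timepoint genotype contrasts,
#' plus temporal contrasts when both timepoints are present), isoform
#' classification, cross-identity pooling, and reference-anchored program
#' scoring of the pooled sets. Writes TSV outputs and a manifest with
#' parameter hash, seeds and package version. Any stage failure aborts with
#' a stage-tagged message.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Invisibly, a list with the in-memory results (`matrix`, `de`,
#'   `calls`, `temporal`, `pooled`, `scores`, `truth`, `outdir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hifsort("[stage %s] %s", name, conditionMessage(e))
    })
  }

  sim_args <- utils::modifyList(list(seed = derive_seed(config$seed, "sim")),
                                config$sim)
  sim <- stage("simulate", simulate_counts(do.call(sim_config, sim_args)))
  m <- sim$matrix
  m$cell_meta <- dplyr::rename(m$cell_meta, true_identity = "identity")

  m <- stage("qc", apply_qc(m, do.call(qc_params, config$qc)))

  an <- config$annotate
  m <- stage("annotate", annotate_cells(
    m, sim$markers, sim$module_a, max_rank = an$max_rank,
    class_threshold = an$class_threshold, n_bins = an$n_bins,
    n_ctrl = an$n_ctrl, seed = derive_seed(config$seed, "annotate")))

  identities <- sort(unique(m$cell_meta$identity))
  de_all <- stage("pseudobulk_de", {
    setNames(lapply(identities, function(id) {
      fit_identity_contrasts(m, id, config$de)
    }), identities)
  })

  calls <- stage("classify", {
    dplyr::bind_rows(lapply(identities, function(id) {
      d <- de_all[[id]]
      classify_dependence(d$vko_con, d$vhko_vko, d$veko_vko, d$vheko_vko,
                          l2fc_min = config$de$l2fc_min,
                          alpha = config$de$alpha)
    }))
  })
  temporal <- NULL
  if (!is.null(de_all[[1]]$vko_con_early)) {
    temporal <- stage("classify_temporal", {
      dplyr::bind_rows(lapply(identities, function(id) {
        d <- de_all[[id]]
        classify_temporal(d$vko_con_early, d$vko_late_early,
                          d$con_late_early, l2fc_min = config$de$l2fc_min,
                          alpha = config$de$alpha)
      }))
    })
  }
  pooled <- stage("pool", pool_categories(calls))

  sc_cfg <- config$score
  scores <- stage("score", {
    out <- list()
    for (nm in c("hif1a", "hif2a")) {
      for (dir in c("up", "down")) {
        genes <- pooled[[nm]]$gene[pooled[[nm]]$direction == dir]
        if (length(genes) < 3) next
        out[[paste(nm, dir, sep = "_")]] <- score_and_scale(
          subset_cells(m, m$cell_meta$timepoint == "late"),
          genes, direction = dir, anchor_ref = sc_cfg$anchor_ref,
          anchor_target = sc_cfg$anchor_target, n_bins = sc_cfg$n_bins,
          n_ctrl = sc_cfg$n_ctrl, seed = derive_seed(config$seed, nm))
      }
    }
    out
  })

  stage("write", {
    readr::write_tsv(calls, file.path(config$outdir, "calls.tsv"))
    if (!is.null(temporal)) {
      readr::write_tsv(temporal, file.path(config$outdir, "temporal.tsv"))
    }
    readr::write_tsv(pooled$conflicts, file.path(config$outdir, "conflicts.tsv"))
    for (nm in names(scores)) {
      readr::write_tsv(tibble::as_tibble(scores[[nm]]),
                       file.path(config$outdir, paste0("scores_", nm, ".tsv")))
    }
    de_flat <- dplyr::bind_rows(lapply(de_all, function(d) {
      dplyr::bind_rows(lapply(d, tidy))
    }))
    readr::write_tsv(de_flat, file.path(config$outdir, "de_results.tsv"))
    cfg_plain <- rapply(unclass(config), unclass, how = "replace")
    manifest <- list(
      package = "hifsort",
      version = as.character(utils::packageVersion("hifsort")),
      r_version = R.version.string,
      seed = config$seed,
      parameter_hash = rlang::hash(cfg_plain),
      parameters = cfg_plain[setdiff(names(cfg_plain), "outdir")],
      n_cells_post_qc = ncol(m$counts),
      identities = identities
    )
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(matrix = m, de = de_all, calls = calls, temporal = temporal,
                 pooled = pooled, scores = scores, truth = sim$truth,
                 outdir = config$outdir))
}
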