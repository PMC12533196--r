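# The knockout-contrast decision ledger: which HIF isoform a Vhl-dependent
# gene requires, and whether its regulation is early or adaptive.

#' Classify HIF isoform dependence from four knockout contrasts
#'
#' A gene is Vhl-dependent when it is regulated (|L2FC| > `l2fc_min`,
#' adjusted p < `alpha`, strict) in VKO vs ConKO. For each knockout contrast
#' X in \{VHKO vs VKO, VEKO vs VKO, VHEKO vs VKO\}, the gene is X-dependent
#' when (i) the contrast is significant (adjusted p < `alpha`), (ii) its
#' L2FC has the opposite sign to the VKO-vs-ConKO L2FC, and (iii) its
#' magnitude is strictly more than half of the VKO-vs-ConKO magnitude.
#' Isoform category: Hif1a- and Epas1-dependent -> `HIF1A_or_HIF2A`;
#' Hif1a only -> `HIF1A_alone`; Epas1 only -> `HIF2A_alone`; neither single
#' knockout but the double -> `HIF1A_plus_HIF2A`; none -> `ambiguous`.
#'
#' @param de_vko_con,de_vhko_vko,de_veko_vko,de_vheko_vko `de_result` tibbles
#'   for the four contrasts on one identity.
#' @param l2fc_min,alpha Regulation thresholds (defaults 1.0 and 0.05).
#' @param half_rule Fraction of the VKO-vs-ConKO magnitude a knockout
#'   reversal must exceed (default 0.5, strict).
#' @return A `dependence_calls` tibble: one row per Vhl-dependent gene with
#'   `gene`, `identity`, `direction`, dependence flags, `category`, and the
#'   four underlying `l2fc_*` columns.
#' @export
classify_dependence <- function(de_vko_con, de_vhko_vko, de_veko_vko,
                                de_vheko_vko, l2fc_min = 1.0, alpha = 0.05,
                                half_rule = 0.5) {
  des <- list(vko_con = de_vko_con, vhko = de_vhko_vko, veko = de_veko_vko,
              vheko = de_vheko_vko)
  if (any(vapply(des, is.null, logical(1)))) {
    stop_hifsort("all four contrasts are required")
  }
  for (nm in names(des)) assert_columns(des[[nm]], c("gene", "l2fc", "padj"), nm)
  identity <- attr(de_vko_con, "identity") %||% "all"

  reg <- call_regulated(de_vko_con, l2fc_min = l2fc_min, alpha = alpha)
  if (nrow(reg) == 0) {
    return(structure(tibble::tibble(
      gene = character(), identity = character(), direction = character(),
      vhl_dependent = logical(), hif1a_dependent = logical(),
      epas1_dependent = logical(), hif1a_epas1_dependent = logical(),
      category = character(), l2fc_vko_con = numeric(), l2fc_vhko = numeric(),
      l2fc_veko = numeric(), l2fc_vheko = numeric()),
      class = c("dependence_calls", class(tibble::tibble()))))
  }
  pick <- function(de, genes) {
    i <- match(genes, de$gene)
    list(l2fc = de$l2fc[i], padj = de$padj[i])
  }
  v <- pick(de_vko_con, reg$gene)
  dep_flag <- function(de) {
    x <- pick(de, reg$gene)
    ok <- !is.na(x$l2fc) & !is.na(x$padj) &
      x$padj < alpha &
      sign(x$l2fc) == -sign(v$l2fc) &
      abs(x$l2fc) > half_rule * abs(v$l2fc)
    list(flag = ok, l2fc = x$l2fc)
  }
  h1 <- dep_flag(de_vhko_vko)
  h2 <- dep_flag(de_veko_vko)
  he <- dep_flag(de_vheko_vko)
  category <- dplyr::case_when(
    h1$flag & h2$flag ~ "HIF1A_or_HIF2A",
    h1$flag & !h2$flag ~ "HIF1A_alone",
    !h1$flag & h2$flag ~ "HIF2A_alone",
    he$flag ~ "HIF1A_plus_HIF2A",
    TRUE ~ "ambiguous"
  )
  out <- tibble::tibble(
    gene = reg$gene, identity = identity, direction = reg$direction,
    vhl_dependent = TRUE, hif1a_dependent = h1$flag,
    epas1_dependent = h2$flag, hif1a_epas1_dependent = he$flag,
    category = category,
    l2fc_vko_con = v$l2fc, l2fc_vhko = h1$l2fc, l2fc_veko = h2$l2fc,
    l2fc_vheko = he$l2fc
  )
  structure(out, class = c("dependence_calls", class(out)))
}

#' Classify early versus adaptive regulation
#'
#' Early genes are regulated in VKO vs ConKO at the early timepoint.
#' Adaptive genes are regulated late vs early in VKO but not late vs early
#' in ConKO. Genes qualifying as both are labelled `both_excluded` and must
#' be dropped from program scoring.
#'
#' @param de_vko_con_early VKO vs ConKO at the early timepoint.
#' @param de_vko_late_early Late vs early within VKO.
#' @param de_con_late_early Late vs early within ConKO.
#' @inheritParams classify_dependence
#' @return Tibble `gene`, `identity`, `temporal`
#'   (`early`/`adaptive`/`both_excluded`), `direction` (from the defining
#'   contrast; for `both_excluded`, from the early contrast).
#' @export
classify_temporal <- function(de_vko_con_early, de_vko_late_early,
                              de_con_late_early, l2fc_min = 1.0,
                              alpha = 0.05) {
  for (d in list(de_vko_con_early, de_vko_late_early, de_con_late_early)) {
    assert_columns(d, c("gene", "l2fc", "padj"), "de")
  }
  identity <- attr(de_vko_con_early, "identity") %||% "all"
  early <- call_regulated(de_vko_con_early, l2fc_min, alpha)
  vko_t <- call_regulated(de_vko_late_early, l2fc_min, alpha)
  con_t <- call_regulated(de_con_late_early, l2fc_min, alpha)
  adaptive <- dplyr::anti_join(vko_t, con_t, by = "gene")
  both <- intersect(early$gene, adaptive$gene)
  dplyr::bind_rows(
    early |> dplyr::filter(!.data$gene %in% both) |>
      dplyr::mutate(temporal = "early"),
    adaptive |> dplyr::filter(!.data$gene %in% both) |>
      dplyr::mutate(temporal = "adaptive"),
    early |> dplyr::filter(.data$gene %in% both) |>
      dplyr::mutate(temporal = "both_excluded")
  ) |>
    dplyr::mutate(identity = identity) |>
    dplyr::select("gene", "identity", "temporal", "direction", "l2fc", "padj")
}

#' Pool isoform-specific calls across identities
#'
#' A gene enters the pooled HIF1A-specific (or HIF2A-specific) set when it is
#' called `HIF1A_alone` (`HIF2A_alone`) in any identity, in the given
#' direction. Genes called HIF1A-specific in one identity and HIF2A-specific
#' in another (same direction) are listed in the conflict report and excluded
#' from both pooled sets, so the pooled sets are disjoint.
#'
#' @param calls A `dependence_calls` tibble (rows from one or more
#'   identities).
#' @return List with `hif1a` and `hif2a` (tibbles `gene`, `direction`) and
#'   `conflicts` (tibble of excluded genes with the identities involved).
#' @export
pool_categories <- function(calls) {
  assert_columns(calls, c("gene", "identity", "direction", "category"), "calls")
  spec <- calls |>
    dplyr::filter(.data$category %in% c("HIF1A_alone", "HIF2A_alone"))
  conflicts <- spec |>
    dplyr::distinct(.data$gene, .data$direction, .data$category, .data$identity) |>
    dplyr::group_by(.data$gene, .data$direction) |>
    dplyr::summarise(n_cat = dplyr::n_distinct(.data$category),
                     identities = paste(unique(.data$identity), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cat > 1) |>
    dplyr::select("gene", "direction", "identities")
  excl <- paste(conflicts$gene, conflicts$direction)
  pooled <- function(cat) {
    spec |>
      dplyr::filter(.data$category == cat,
                    !paste(.data$gene, .data$direction) %in% excl) |>
      dplyr::distinct(.data$gene, .data$direction)
  }
  list(hif1a = pooled("HIF1A_alone"), hif2a = pooled("HIF2A_alone"),
       conflicts = conflicts)
}

#' Spearman anti-correlation diagnostic
#'
#' Correlates the VHEKO-vs-VKO L2FC vector against the VKO-vs-ConKO L2FC
#' vector over a gene subset. For fully HIF-dependent regulation the two are
#' strongly anti-correlated (rho < -0.8 in the motivating analysis).
#'
#' @param de_vheko_vko,de_vko_con `de_result` tibbles.
#' @param genes Gene subset (>= 10 genes).
#' @return List with `rho`, `p`, `n`.
#' @export
anticorrelation_diagnostic <- function(de_vheko_vko, de_vko_con, genes) {
  x <- de_vko_con$l2fc[match(genes, de_vko_con$gene)]
  y <- de_vheko_vko$l2fc[match(genes, de_vheko_vko$gene)]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10) stop_hifsort("need >= 10 genes with finite l2fc in both contrasts")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warn_hifsort("constant l2fc vector; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
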