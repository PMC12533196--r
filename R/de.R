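# Negative-binomial Wald differential expression on pseudo-bulk samples.
#
# Per gene: NB log-link GLM with design ~ sex + factor-of-interest and
# offset log(size factor); dispersion by per-gene method of moments with
# empirical-Bayes shrinkage toward a fitted mean-dispersion trend
# alpha(mu) = a0 + a1/mu; Wald z = beta/SE with a two-sided normal p value;
# BH adjustment across genes with no independent filtering.

# Method-of-moments dispersion on normalized counts, floored. The shot-noise
# term of Var(K/sf) is mu * mean(1/sf), not mu, so the size-factor harmonic
# term xi is subtracted to avoid inflating the biological dispersion.
mom_dispersion <- function(norm_counts, size_factors = NULL, groups = NULL,
                           floor = 1e-8) {
  xi <- if (is.null(size_factors)) 1 else mean(1 / size_factors)
  mu <- rowMeans(norm_counts)
  if (is.null(groups)) {
    v <- apply(norm_counts, 1, stats::var)
  } else {
    # pooled within-group variance so design effects (sex, genotype) do not
    # masquerade as dispersion
    groups <- factor(groups)
    keep <- levels(groups)[table(groups) >= 2]
    sse <- 0
    df <- 0
    for (lv in keep) {
      j <- groups == lv
      ctr <- norm_counts[, j, drop = FALSE] -
        rowMeans(norm_counts[, j, drop = FALSE])
      sse <- sse + rowSums(ctr^2)
      df <- df + sum(j) - 1
    }
    if (df < 1) stop_hifsort("not enough replication to estimate dispersion")
    v <- sse / df
  }
  a <- (v - mu * xi) / mu^2
  a[!is.finite(a)] <- floor
  a
}

# Fit alpha(mu) = a0 + a1/mu to the *unfloored* method-of-moments estimates:
# genes are binned by mean expression and the bin means (which keep the
# negative-noise genes, so they are unbiased for the true dispersion) are
# regressed on 1/mu. Flooring before this fit would select positive noise
# and inflate the trend at low expression.
fit_dispersion_trend <- function(mu, alpha_raw, floor = 1e-8, n_bins = 20) {
  ok <- is.finite(alpha_raw) & mu > 0
  if (sum(ok) < 20) {
    return(c(a0 = max(mean(pmax(alpha_raw[ok], floor)), floor), a1 = 0))
  }
  bin <- dplyr::ntile(rank(mu[ok], ties.method = "first"),
                      min(n_bins, max(2, floor(sum(ok) / 10))))
  ab <- tapply(alpha_raw[ok], bin, mean)
  mb <- tapply(mu[ok], bin, mean)
  nb <- tapply(mu[ok], bin, length)
  fit <- stats::lm(ab ~ I(1 / mb), weights = nb)
  c(a0 = max(unname(coef(fit)[1]), floor),
    a1 = max(unname(coef(fit)[2]), 0))
}

# EB shrinkage of log dispersion toward the trend. The sampling variance of
# the per-gene log estimate is approximated by trigamma(k), k = (m - p)/2,
# and the log of the (roughly mean-unbiased) raw estimate is corrected for
# its Jensen bias, log(k) - digamma(k), before shrinking; the prior
# log-variance is fixed at 0.25.
shrink_dispersion <- function(alpha_raw, mu, m, p, trend,
                              prior_logvar = 0.25, floor = 1e-8) {
  alpha_tr <- pmax(trend["a0"] + trend["a1"] / pmax(mu, 1e-8), floor)
  k <- max((m - p) / 2, 0.5)
  s2_obs <- trigamma(k)
  w <- (1 / s2_obs) / (1 / s2_obs + 1 / prior_logvar)
  # negative/near-zero raw estimates carry "below trend", not "zero":
  # floor them relative to the trend before taking logs
  lo <- pmax(floor, 0.05 * alpha_tr)
  log_raw <- log(pmax(alpha_raw, lo)) + (log(k) - digamma(k))
  exp(w * log_raw + (1 - w) * log(alpha_tr))
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per gene, an NB GLM with log link, design
#' `~ sex + <contrast factor>` and `log(size factor)` offsets, on the samples
#' belonging to the two contrasted levels. The contrast coefficient is
#' reported as a log2 fold change with its Wald standard error, two-sided
#' normal p value, and BH-adjusted p across genes (no independent filtering).
#'
#' @param pb A `pseudobulk` object; size factors are estimated if absent.
#' @param contrast Length-3 character vector
#'   `c(factor, numerator_level, denominator_level)`, e.g.
#'   `c("genotype", "VKO", "ConKO")` or `c("timepoint", "late", "early")`.
#' @param design Additional covariates; currently `"sex"` (default) or
#'   `character()` for none. Sex is dropped automatically (with a warning)
#'   when it is confounded or constant in the contrasted samples.
#' @param min_reps Minimum samples per contrasted level (default 2).
#' @param prior_logvar Prior log-variance of the dispersion shrinkage
#'   (default 0.25).
#' @return A `de_result` tibble: `gene`, `base_mean`, `l2fc`, `se`, `stat`,
#'   `p`, `padj`, `flag`, with attributes `contrast` and `identity`.
#' @export
fit_de <- function(pb, contrast, design = "sex", min_reps = 2,
                   prior_logvar = 0.25) {
  stopifnot(inherits(pb, "pseudobulk"), length(contrast) == 3)
  if (is.null(pb$size_factors)) pb <- estimate_size_factors(pb)
  fac <- contrast[1]; num <- contrast[2]; den <- contrast[3]
  assert_columns(pb$sample_meta, fac, "sample_meta")

  keep <- pb$sample_meta[[fac]] %in% c(num, den)
  meta <- pb$sample_meta[keep, , drop = FALSE]
  counts <- pb$counts[, keep, drop = FALSE]
  sf <- pb$size_factors[keep]
  n_num <- sum(meta[[fac]] == num); n_den <- sum(meta[[fac]] == den)
  if (n_num < min_reps || n_den < min_reps) {
    stop_hifsort("contrast %s_vs_%s needs >= %d samples per level (have %d vs %d)",
                 num, den, min_reps, n_num, n_den)
  }
  meta$.grp <- stats::relevel(factor(meta[[fac]], levels = c(den, num)),
                              ref = den)
  covars <- intersect(design, names(meta))
  fml <- "~ .grp"
  if ("sex" %in% covars) {
    confounded <- length(unique(meta$sex)) < 2 ||
      qr(stats::model.matrix(~ sex + .grp, meta))$rank < 3
    if (confounded) {
      warn_hifsort("sex covariate constant or confounded; dropping from design")
    } else {
      fml <- "~ sex + .grp"
    }
  }
  X <- stats::model.matrix(stats::as.formula(fml), meta)
  if (qr(X)$rank < ncol(X)) stop_hifsort("design matrix is rank deficient")
  coef_name <- paste0(".grp", num)

  norm <- sweep(counts, 2, sf, "/")
  # dispersion from within-group variance; prefer the full design cells
  # (sex x group), falling back to the contrast groups alone when the design
  # cells have no replication
  design_cells <- interaction(as.data.frame(X[, -1, drop = FALSE]), drop = TRUE)
  disp_groups <- design_cells
  df_of <- function(g) sum(pmax(table(g) - 1, 0))
  if (df_of(disp_groups) < 2) disp_groups <- factor(meta$.grp)
  alpha_raw <- mom_dispersion(norm, size_factors = sf, groups = disp_groups)
  mu_bar <- rowMeans(norm)
  trend <- fit_dispersion_trend(mu_bar, alpha_raw)
  df_disp <- sum(pmax(table(disp_groups) - 1, 0))
  alpha <- shrink_dispersion(alpha_raw, mu_bar, m = ncol(counts),
                             p = ncol(counts) - max(df_disp, 1),
                             trend = trend, prior_logvar = prior_logvar)
  alpha <- pmin(alpha, 50)

  off <- log(sf)
  G <- nrow(counts)
  l2fc <- se <- stat <- p <- numeric(G)
  flag <- character(G)
  ci <- match(coef_name, colnames(X))
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) {
      l2fc[g] <- 0; se[g] <- NA_real_; stat[g] <- 0; p[g] <- 1
      flag[g] <- "all_zero"
      next
    }
    fam <- MASS::negative.binomial(theta = 1 / alpha[g])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(coef(fit)))) {
      l2fc[g] <- NA_real_; se[g] <- NA_real_; stat[g] <- NA_real_; p[g] <- 1
      flag[g] <- "fit_failed"
      next
    }
    beta <- coef(fit)[ci]
    p1 <- seq_len(ncol(X))
    cov <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(cov)) {
      l2fc[g] <- beta / log(2); se[g] <- NA_real_; stat[g] <- NA_real_
      p[g] <- 1; flag[g] <- "se_failed"
      next
    }
    se_nat <- sqrt(cov[ci, ci])
    l2fc[g] <- beta / log(2)
    se[g] <- se_nat / log(2)
    stat[g] <- beta / se_nat
    p[g] <- 2 * stats::pnorm(-abs(stat[g]))
    if (!fit$converged) flag[g] <- "not_converged"
  }
  res <- tibble::tibble(
    gene = rownames(counts) %||% paste0("g", seq_len(G)),
    base_mean = mu_bar, l2fc = l2fc, se = se, stat = stat, p = p,
    padj = stats::p.adjust(p, method = "BH"), flag = flag
  )
  structure(res, class = c("de_result", class(res)),
            contrast = paste0(num, "_vs_", den), factor = fac,
            identity = pb$sample_meta$identity[1],
            dispersion_trend = trend)
}

#' Call regulated genes from a DE result
#'
#' Up: `l2fc > l2fc_min` and `padj < alpha`; down: `l2fc < -l2fc_min` and
#' `padj < alpha`. Both inequalities strict.
#'
#' @param de A `de_result`.
#' @param l2fc_min Absolute log2 fold-change threshold (default 1.0).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Tibble `gene`, `direction` (`"up"`/`"down"`), `l2fc`, `padj`.
#' @export
call_regulated <- function(de, l2fc_min = 1.0, alpha = 0.05) {
  assert_columns(de, c("gene", "l2fc", "padj"), "de")
  de |>
    dplyr::filter(!is.na(.data$l2fc), !is.na(.data$padj),
                  abs(.data$l2fc) > l2fc_min, .data$padj < alpha) |>
    dplyr::mutate(direction = ifelse(.data$l2fc > 0, "up", "down")) |>
    dplyr::select("gene", "direction", "l2fc", "padj")
}
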