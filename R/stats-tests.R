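# Group-comparison statistics used on per-mouse summaries: one-way MANOVA
# with Wilks lambda (frequency distributions) and Kruskal-Wallis with Dunn
# post hoc (medians).

# Wilks lambda and Rao's F approximation for a one-way MANOVA.
wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  g <- nlevels(groups); p <- ncol(X); N <- nrow(X)
  if (g < 2) stop_hifsort("need >= 2 groups")
  grand <- colMeans(X)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lv in levels(groups)) {
    Xi <- X[groups == lv, , drop = FALSE]
    ni <- nrow(Xi)
    mi <- colMeans(Xi)
    H <- H + ni * tcrossprod(mi - grand)
    ctr <- sweep(Xi, 2, mi)
    E <- E + crossprod(ctr)
  }
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0) {
    stop_hifsort("singular within-group matrix; merge bins or drop variables")
  }
  lambda <- detE / det(E + H)
  q <- g - 1
  m_e <- N - g
  t <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- m_e + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t - (p * q - 2) / 2
  lam_t <- lambda^(1 / t)
  f_stat <- (1 - lam_t) / lam_t * df2 / df1
  p_val <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(lambda = lambda, f = f_stat, df1 = df1, df2 = df2, p = p_val,
       E = E, H = H)
}

#' Compare per-mouse frequency distributions (MANOVA, Wilks lambda)
#'
#' Each mouse's neighbor-count frequency vector is converted to proportions
#' and the last bin dropped (the vector is compositional), then treated as
#' one multivariate observation in a one-way MANOVA. Wilks lambda
#' `det(E)/det(E+H)` is converted to a p value via Rao's F approximation.
#' Pairwise group comparisons are Bonferroni-adjusted over the requested
#' pairs.
#'
#' @param freq Per-mouse frequency matrix or the `per_mouse` tibble from
#'   [neighbor_counts()] (its `freq_*` columns are used).
#' @param groups Group label per mouse (e.g. `"VKO_early"`).
#' @param pairs Optional list of length-2 character vectors naming the
#'   pairwise comparisons to run; default: the overall test only.
#' @return A `manova_wilks` list: `lambda`, `f`, `df1`, `df2`, `p`, and
#'   (when `pairs` given) `pairwise` tibble with Bonferroni-adjusted p.
#' @export
compare_distributions <- function(freq, groups, pairs = NULL) {
  if (is.data.frame(freq)) {
    fc <- grep("^freq_", names(freq), value = TRUE)
    if (length(fc) > 0) freq <- as.matrix(freq[, fc, drop = FALSE])
    else freq <- as.matrix(freq)
  }
  freq <- as.matrix(freq)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop_hifsort("need >= 2 mice per group")
  prop <- freq / rowSums(freq)
  # constant bins (e.g. structurally empty high bins) carry no information;
  # then one remaining column is dropped because proportions are compositional
  keep_col <- apply(prop, 2, stats::sd) > 0
  X <- prop[, keep_col, drop = FALSE]
  if (ncol(X) < 2) stop_hifsort("need >= 2 bins with variation")
  X <- X[, -ncol(X), drop = FALSE]
  # with only two informative bins this degenerates to a univariate one-way
  # comparison; the Wilks/Rao formulas remain valid at p = 1
  overall <- wilks_lambda(X, groups)
  out <- list(lambda = overall$lambda, f = overall$f, df1 = overall$df1,
              df2 = overall$df2, p = overall$p)
  if (!is.null(pairs)) {
    rows <- purrr::map_dfr(pairs, function(pr) {
      keep <- groups %in% pr
      w <- wilks_lambda(X[keep, , drop = FALSE], droplevels(groups[keep]))
      tibble::tibble(group1 = pr[1], group2 = pr[2], lambda = w$lambda,
                     f = w$f, p = w$p)
    })
    rows$p_adj <- pmin(rows$p * length(pairs), 1)
    out$pairwise <- rows
  }
  structure(out, class = "manova_wilks")
}

#' @export
print.manova_wilks <- function(x, ...) {
  cat(sprintf("<manova_wilks> Lambda = %.4f, F(%g, %.1f) = %.3f, p = %.4g\n",
              x$lambda, x$df1, x$df2, x$f, x$p))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Compare per-mouse values (Kruskal-Wallis with Dunn post hoc)
#'
#' The omnibus H statistic (with tie correction) comes from
#' [stats::kruskal.test()]; Dunn z statistics for the requested pairs use
#' the rank-mean formula with the tie term
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))`, with two-sided normal p values
#' Bonferroni-adjusted over the requested pairs (Dunn's correction).
#'
#' @param values Numeric vector (one observation per mouse).
#' @param groups Group label per observation.
#' @param pairs List of length-2 character vectors; default all pairs.
#' @return A `kw_dunn` list: `h`, `df`, `p`, `pairwise` tibble
#'   (`group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
compare_medians <- function(values, groups, pairs = NULL) {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop_hifsort("every group must be non-empty and >= 2 groups required")
  }
  if (length(values) < 3) stop_hifsort("need >= 3 observations")
  if (length(unique(values)) == 1) {
    # fully tied data: no evidence of any difference
    kw <- list(statistic = c(H = 0), parameter = c(df = nlevels(groups) - 1),
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
  }

  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  if (is.null(pairs)) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- purrr::map_dfr(pairs, function(pr) {
    sd_ij <- sqrt((N * (N + 1) / 12 - tie_term) *
                    (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- if (sd_ij == 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / sd_ij
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  rows$p_adj <- pmin(rows$p * length(pairs), 1)
  structure(list(h = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = rows),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("<kw_dunn> H = %.3f (df = %d), p = %.4g\n", x$h, x$df, x$p))
  print(x$pairwise)
  invisible(x)
}
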