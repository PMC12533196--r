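# Internal helpers shared across modules.

# Stop with a consistent error class so callers can test on it.
stop_hifsort <- function(msg, ..., class = "hifsort_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

warn_hifsort <- function(msg, ...) {
  rlang::warn(sprintf(msg, ...))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_hifsort("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Derive a child seed from a user seed and a stage label, kept < 2^31.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# log1p CP10K normalization used for binning and module scores.
lognorm_counts <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  dimnames(out) <- dimnames(counts)
  log1p(out)
}
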