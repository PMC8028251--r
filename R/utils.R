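# Internal helpers shared across modules.

# Upper-triangle (i < j) of a square matrix as a vector, column-major order.
upper_vec <- function(m) m[upper.tri(m)]

# Stop with a formatted message.
abort <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic entry points route through this so that results
# are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Permutation p-value with the (1 + b) / (1 + m) convention, so p is never 0.
perm_pvalue <- function(null_stats, observed, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  b <- if (tail == "greater") sum(null_stats >= observed) else sum(null_stats <= observed)
  (1 + b) / (1 + length(null_stats))
}

check_samples_match <- function(ids1, ids2, what = "distance matrices") {
  if (length(ids1) != length(ids2) || !all(ids1 == ids2)) {
    abort("sample ids of the two %s do not match (reorder or subset first)", what)
  }
  invisible(TRUE)
}
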