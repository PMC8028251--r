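# Dissimilarity construction and matrix-level permutation statistics:
# Bray-Curtis, standardized chemistry Euclidean distance, Mantel test,
# PERMANOVA pseudo-F, one-way ANOVA F.

#' Construct a labeled distance matrix
#'
#' @param m square symmetric numeric matrix with zero diagonal and matching
#'   row/column names (the ordered sample ids).
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return An object of class `distance_matrix` with fields `d` (matrix),
#'   `sample_ids`, `metric`.
#' @export
distance_matrix <- function(m, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (is.null(rownames(m))) abort("distance matrix needs sample ids as dimnames")
  if (!all(rownames(m) == colnames(m))) abort("row/column ids disagree")
  if (max(abs(m - t(m))) > 1e-12) abort("matrix not symmetric to 1e-12")
  if (max(abs(diag(m))) > 1e-12) abort("diagonal must be zero")
  if (metric == "bray_curtis" && (min(m) < -1e-12 || max(m) > 1 + 1e-12)) {
    abort("Bray-Curtis entries must lie in [0, 1]")
  }
  diag(m) <- 0
  structure(list(d = m, sample_ids = rownames(m), metric = metric),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d samples\n", x$metric,
              length(x$sample_ids)))
  invisible(x)
}

#' Write / read a distance matrix as square TSV
#'
#' @param d a [distance_matrix()].
#' @param path destination/source file.
#' @name distance_matrix_io
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = d$sample_ids, d$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param metric metric tag to attach on read.
#' @rdname distance_matrix_io
#' @export
read_distance_matrix <- function(path, metric = c("bray_curtis", "euclidean")) {
  raw <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  m <- (m + t(m)) / 2  # absorb round-off from decimal serialization
  distance_matrix(m, match.arg(metric))
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over taxa, in \[0, 1\].
#'
#' @param t a [rel_abund_table()] (or any non-negative taxa x samples
#'   matrix with at least two samples).
#' @return A [distance_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis <- function(t) {
  abund <- if (inherits(t, "rel_abund_table")) t$abund else as.matrix(t)
  if (ncol(abund) < 2) abort("need at least 2 samples")
  if (min(abund) < 0) abort("abundances must be non-negative")
  zero <- colSums(abund) == 0
  if (sum(zero) >= 2) {
    abort("Bray-Curtis undefined for the all-zero sample pair(s): %s",
          paste(colnames(abund)[zero], collapse = ", "))
  }
  m <- as.matrix(vegan::vegdist(t(abund), method = "bray"))
  distance_matrix(m, "bray_curtis")
}

#' Euclidean distance over straw chemistry components
#'
#' Computes pairwise Euclidean distances over the four straw components.
#' By default each component is z-standardized across samples first, so
#' components measured on different scales contribute comparably; a
#' zero-variance component is dropped with a warning.
#'
#' @param c a [chemistry_table()].
#' @param standardize z-standardize each component first (default `TRUE`).
#' @return A [distance_matrix()] with metric `"euclidean"`.
#' @export
chemistry_distance <- function(c, standardize = TRUE) {
  stopifnot(inherits(c, "chemistry_table"))
  comp <- as.matrix(as.data.frame(c)[, CHEMISTRY_COMPONENTS])
  rownames(comp) <- c$sample_id
  if (nrow(comp) < 2) abort("need at least 2 samples")
  if (standardize) {
    sds <- apply(comp, 2, sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping zero-variance component(s): %s",
                      paste(colnames(comp)[sds == 0], collapse = ", ")))
      comp <- comp[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
      if (ncol(comp) == 0) abort("all components have zero variance")
    }
    comp <- scale(comp)
  }
  m <- as.matrix(dist(comp, method = "euclidean"))
  distance_matrix(m, "euclidean")
}

# Rank-transform the off-diagonal entries of a symmetric matrix in place
# (used for the Spearman variant of the Mantel test). Ranking depends only
# on the multiset of values, so it commutes with sample relabeling.
rank_offdiag <- function(m) {
  ut <- upper.tri(m)
  r <- rank(m[ut])
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  out[ut] <- r
  out <- out + t(out)
  out
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices and assesses
#' significance by jointly permuting the sample labels (rows and columns)
#' of the second matrix. One-tailed for positive association, with the
#' (1 + b) / (1 + m) p-value convention.
#'
#' @param d1,d2 [distance_matrix()] objects over the same ordered samples.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed (mandatory for reproducibility).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `seed`,
#'   `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed, method = c("pearson",
                                                               "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"),
            n_perm >= 99)
  check_samples_match(d1$sample_ids, d2$sample_ids)
  x <- d1$d
  y <- d2$d
  if (method == "spearman") {
    x <- rank_offdiag(x)
    y <- rank_offdiag(y)
  }
  ut <- upper.tri(x)
  xv <- x[ut]
  xc <- xv - mean(xv)
  yv <- y[ut]
  denom <- sqrt(sum(xc^2) * sum((yv - mean(yv))^2))
  if (denom == 0) abort("zero variance in one of the distance matrices")
  r_obs <- sum(xc * yv) / denom
  n <- nrow(x)
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    sum(xc * y[p, p][ut]) / denom
  }, numeric(1)))
  structure(list(r = r_obs, p = perm_pvalue(null_r, r_obs, "greater"),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 method = method),
            class = "mantel_result")
}

# Within-group sum of squared distances divided by group sizes
# (Anderson's partition), given the squared-distance matrix.
ss_within <- function(d2mat, groups) {
  total <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    total <- total + sum(d2mat[idx, idx]) / (2 * length(idx))
  }
  total
}

#' PERMANOVA pseudo-F from a distance matrix
#'
#' One-way permutational multivariate analysis of variance: partitions the
#' total sum of squared distances into between- and within-group
#' components (SS_total = sum of squared distances / n; SS_within from
#' within-group pairs scaled by group size) and forms
#' F = (SS_between / df_between) / (SS_within / df_within). Significance by
#' permutation of group labels. Perfect separation (zero within-group
#' distance) is reported as an `Inf` sentinel.
#'
#' @param d a [distance_matrix()].
#' @param groups group label per sample; at least 2 groups, each with at
#'   least 2 samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return List of class `permanova_result`: `pseudo_F`, `p`, `df_between`,
#'   `df_within`, `n_perm`, `seed`. No multiple-testing correction is
#'   applied to repeated calls; metadata field `correction = "none"` makes
#'   this explicit.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  stopifnot(inherits(d, "distance_matrix"))
  groups <- as.character(groups)
  if (length(groups) != length(d$sample_ids)) {
    abort("one group label per sample required")
  }
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort("singleton group(s): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  n <- length(groups)
  g <- length(sizes)
  d2mat <- d$d^2
  ss_tot <- sum(d2mat) / (2 * n)
  df_b <- g - 1L
  df_w <- n - g
  f_of <- function(lab) {
    ssw <- ss_within(d2mat, lab)
    ssb <- ss_tot - ssw
    if (ssw <= 1e-12 * max(ss_tot, 1)) return(Inf)
    (ssb / df_b) / (ssw / df_w)
  }
  f_obs <- f_of(groups)
  null_f <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    f_of(groups[sample.int(n)])
  }, numeric(1)))
  structure(list(pseudo_F = f_obs, p = perm_pvalue(null_f, f_obs, "greater"),
                 df_between = df_b, df_within = df_w,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 correction = "none"),
            class = "permanova_result")
}

#' Classical one-way ANOVA F score
#'
#' F = MS_between / MS_within with its p-value from the F distribution.
#' Used to compare the variability of community metrics across
#' decomposition stages. Zero within-group variance in every group yields
#' an `Inf` sentinel.
#'
#' @param values numeric response, one per sample.
#' @param groups group (stage) label per sample.
#' @return List of class `anova_f`: `F`, `p`, `df_between`, `df_within`.
#' @export
anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  n <- length(values)
  g <- nlevels(groups)
  if (n - g < 2) abort("need at least 2 within-group degrees of freedom")
  gm <- tapply(values, groups, mean)
  sizes <- tabulate(groups)
  grand <- mean(values)
  ms_b <- sum(sizes * (gm - grand)^2) / (g - 1)
  ms_w <- sum((values - gm[as.integer(groups)])^2) / (n - g)
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / ms_w
  structure(list(F = f,
                 p = pf(f, g - 1, n - g, lower.tail = FALSE),
                 df_between = g - 1L, df_within = n - g),
            class = "anova_f")
}
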