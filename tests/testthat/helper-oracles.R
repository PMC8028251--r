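# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (double loops, closed forms) and share no code with
# the package implementations they check.

oracle_bray_curtis <- function(mat) {
  n <- ncol(mat)
  out <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0
      den <- 0
      for (k in seq_len(nrow(mat))) {
        num <- num + abs(mat[k, i] - mat[k, j])
        den <- den + mat[k, i] + mat[k, j]
      }
      out[i, j] <- num / den
    }
  }
  out
}

oracle_euclidean <- function(mat) {
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sqrt(sum((mat[i, ] - mat[j, ])^2))
    }
  }
  out
}

oracle_ols_slope <- function(x, y) cov(x, y) / var(x)

# Anderson's one-way pseudo-F computed by explicit pair enumeration.
oracle_permanova_f <- function(dmat, groups) {
  n <- length(groups)
  ss_tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_tot <- ss_tot + dmat[i, j]^2
  }
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) acc <- acc + dmat[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + acc / length(idx)
  }
  g <- length(unique(groups))
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}

oracle_rpkm <- function(count, length_bp, total) {
  count / (length_bp / 1000) / (total / 1e6)
}

# Z-score a phylum x stage panel over its pooled entries, then SD per row.
oracle_zscore_sd <- function(panel) {
  z <- (panel - mean(panel)) / sd(as.vector(panel))
  apply(z, 1, sd)
}

# small random count fixture with full metadata
fixture_count_table <- function(n_taxa = 5, n_samples = 4, seed = 11,
                                lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa,
                dimnames = list(paste0("t", seq_len(n_taxa)),
                                paste0("s", seq_len(n_samples))))
    meta <- data.frame(sample_id = colnames(m), site = "CS",
                       stage_weeks = rep_len(c(1, 2), n_samples),
                       replicate = seq_len(n_samples),
                       fertility = "high")
    count_table(m, meta)
  })
}

fixture_taxonomy <- function(ids, phylum, family = NULL) {
  fam <- family %||% rep(NA_character_, length(ids))
  # keep lineages gap-free: rows with a family need class and order too
  cls <- ifelse(is.na(fam), NA_character_, paste0(phylum, "_c"))
  ord <- ifelse(is.na(fam), NA_character_, paste0(phylum, "_o"))
  taxonomy_map(data.frame(feature_id = ids, domain = "Bacteria",
                          phylum = phylum, class = cls, order = ord,
                          family = fam, genus = NA, species = NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_distance_matrix <- function(n, seed, metric = "euclidean",
                                   dims = 3) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * dims), n)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
    if (metric == "bray_curtis") m <- m / (max(m) + 0.1)
    distance_matrix(m, metric)
  })
}

# correlation_matrix object from a hand-built matrix (bypasses the
# abundance route so planted structures can be exact)
hand_correlation <- function(r, method = "pearson") {
  structure(list(r = r, method = method, min_prevalence = 1,
                 n_samples = NA_integer_,
                 abundance = setNames(rep(1 / nrow(r), nrow(r)),
                                      rownames(r))),
            class = "correlation_matrix")
}

# adjacency matrix (0/1, possibly signed correlations) -> signed_network
network_from_adjacency <- function(adj, threshold = 0.5) {
  r <- adj
  diag(r) <- 1
  build_network(hand_correlation(r), threshold)
}

# two-group niche-breadth community fixture used by contrast tests
fixture_two_group_study <- function(seed, sigma_a = 1, sigma_b = 1,
                                    reps = 4L, n_taxa = 30L,
                                    depth = 2000L) {
  tr <- simulation_truth(seed = seed, sites = "CS",
                         stages = c(1, 2, 4, 8, 16), reps = reps,
                         groups = c(A = sigma_a, B = sigma_b),
                         n_taxa_per_group = n_taxa, depth = depth)
  chem <- simulate_chemistry(tr)
  cmty <- simulate_communities(chem, tr)
  rel <- to_relative_abundance(cmty$counts)
  list(
    chem_d = chemistry_distance(chem),
    a = subset_by_lineage(rel, cmty$taxonomy, c(phylum = "A"),
                          renormalize = TRUE),
    b = subset_by_lineage(rel, cmty$taxonomy, c(phylum = "B"),
                          renormalize = TRUE))
}
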