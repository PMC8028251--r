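# Random-matrix-theory thresholded co-occurrence networks: correlation
# matrices with a prevalence filter, eigenvalue unfolding, nearest-neighbor
# spacing distribution (NNSD) goodness of fit, threshold selection at the
# Wigner-to-Poisson transition, signed network construction, topology
# indices and focal-group link accounting.

#' Pairwise taxon correlation matrix with a prevalence filter
#'
#' Drops taxa detected (abundance > 0) in fewer than `min_prevalence` of
#' samples, then correlates abundance profiles across samples. Optionally
#' log-transforms abundances first with a pseudocount of half the smallest
#' nonzero value.
#'
#' @param t a [rel_abund_table()] with at least 8 samples.
#' @param min_prevalence minimum detection fraction in (0, 1\]; default 0.5
#'   (present in more than half the samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform log(x + pseudocount) before correlating.
#' @return List of class `correlation_matrix`: `r` (taxa x taxa), `method`,
#'   `min_prevalence`, `n_samples`, `abundance` (mean relative abundance
#'   per kept taxon).
#' @export
correlation_matrix <- function(t, min_prevalence = 0.5,
                               method = c("pearson", "spearman"),
                               log_transform = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(t, "rel_abund_table"))
  abund <- t$abund
  if (ncol(abund) < 8) abort("need at least 8 samples for co-occurrence")
  if (min_prevalence <= 0 || min_prevalence > 1) {
    abort("min_prevalence must lie in (0, 1]")
  }
  prev <- rowMeans(abund > 0)
  keep <- prev >= min_prevalence
  if (sum(keep) < 2) abort("fewer than 2 taxa pass the prevalence filter")
  m <- abund[keep, , drop = FALSE]
  if (log_transform) {
    pc <- min(m[m > 0]) / 2
    m <- log(m + pc)
  }
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort("constant abundance profile(s) after filtering: %s",
          paste(rownames(m)[sds == 0], collapse = ", "))
  }
  r <- cor(base::t(m), method = method)
  structure(list(r = r, method = method, min_prevalence = min_prevalence,
                 n_samples = ncol(abund), abundance = rowMeans(m)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (%s): %d taxa over %d samples\n",
              x$method, nrow(x$r), x$n_samples))
  invisible(x)
}

#' Unfold a spectrum to unit mean level spacing
#'
#' Maps sorted eigenvalues through a smooth fit of the cumulative spectral
#' density (a smoothing spline on the empirical CDF, made monotone) so the
#' mean nearest-neighbor spacing of the output is 1. Unfolding removes the
#' system-specific global density so that spacing statistics can be
#' compared with the universal Poisson and GOE ensembles.
#'
#' @param eigs numeric vector of at least 20 eigenvalues (any order).
#' @param smoothing_df degrees of freedom of the smoothing spline
#'   (default 10).
#' @return Sorted unfolded eigenvalues (same length as `eigs`).
#' @export
unfold_eigenvalues <- function(eigs, smoothing_df = 10) {
  eigs <- sort(as.numeric(eigs))
  n <- length(eigs)
  if (n < 20) abort("need at least 20 eigenvalues to unfold")
  if (max(eigs) - min(eigs) < 1e-12) abort("degenerate spectrum: all equal")
  # empirical CDF at each eigenvalue; collapse ties to their mean height
  ecdf_y <- seq_len(n) / n
  ux <- unique(eigs)
  uy <- vapply(split(ecdf_y, match(eigs, ux)), mean, numeric(1))
  df <- min(smoothing_df, length(ux) - 1)
  fit <- if (length(ux) >= 4) {
    smooth.spline(ux, uy, df = max(2, df))
  } else {
    NULL
  }
  smoothed <- if (is.null(fit)) {
    stats::approx(ux, uy, xout = eigs)$y
  } else {
    predict(fit, eigs)$y
  }
  unfolded <- n * cummax(smoothed)  # enforce monotonicity
  sort(unfolded)
}

# Wigner surmise (GOE) distribution functions.
wigner_cdf <- function(d) 1 - exp(-pi * d^2 / 4)
wigner_quantile <- function(u) sqrt(-4 * log(1 - u) / pi)

#' Goodness of fit of a spacing distribution to Poisson and GOE laws
#'
#' Tests the nearest-neighbor spacing histogram against the Poisson law
#' P(d) = exp(-d) (uncorrelated spectrum) and the GOE Wigner surmise
#' P(d) = (pi d / 2) exp(-pi d^2 / 4) (correlated, random-matrix
#' spectrum). Chi-square over bins covering \[0, 3\] (plus an open tail
#' bin), merged so every bin has expected count >= 5; falls back to a
#' Kolmogorov-Smirnov test when fewer than 5 usable bins remain.
#'
#' @param spacings strictly positive spacings of unfolded eigenvalues
#'   (at least 30).
#' @return List with `chi2_poisson`, `p_poisson`, `chi2_goe`, `p_goe`,
#'   `test` (`"chi2"` or `"ks"`), `n`.
#' @export
nnsd_fit <- function(spacings) {
  spacings <- as.numeric(spacings)
  if (length(spacings) < 30) abort("need at least 30 spacings")
  if (any(spacings <= 0)) abort("spacings must be strictly positive")
  n <- length(spacings)
  breaks <- seq(0, 3, by = 0.2)
  edges <- c(breaks, Inf)
  counts <- as.vector(table(cut(spacings, edges, right = TRUE)))
  gof <- function(cdf) {
    expected <- n * diff(cdf(edges))
    # merge adjacent bins until each expected count is >= 5
    obs <- counts
    exp_ <- expected
    i <- 1
    while (i <= length(exp_)) {
      if (exp_[i] < 5 && length(exp_) > 1) {
        j <- if (i == length(exp_)) i - 1 else i + 1
        exp_[j] <- exp_[j] + exp_[i]
        obs[j] <- obs[j] + obs[i]
        exp_ <- exp_[-i]
        obs <- obs[-i]
        if (i > length(exp_)) i <- length(exp_)
      } else {
        i <- i + 1
      }
    }
    if (length(exp_) < 5) {
      ks <- suppressWarnings(ks.test(spacings, function(q) cdf(q)))
      return(list(chi2 = unname(ks$statistic), p = ks$p.value, test = "ks"))
    }
    chi2 <- sum((obs - exp_)^2 / exp_)
    list(chi2 = chi2, p = pchisq(chi2, df = length(exp_) - 1,
                                 lower.tail = FALSE), test = "chi2")
  }
  pois <- gof(function(q) ifelse(q < 0, 0, 1 - exp(-pmax(q, 0))))
  goe <- gof(function(q) ifelse(q < 0, 0, wigner_cdf(pmax(q, 0))))
  list(chi2_poisson = pois$chi2, p_poisson = pois$p,
       chi2_goe = goe$chi2, p_goe = goe$p,
       test = pois$test, n = n)
}

# Spectrum -> NNSD fit for one thresholded correlation matrix. Taxa with no
# surviving off-diagonal entry are dropped (they are isolated in the
# network); degenerate (tied) eigenvalues are collapsed before unfolding so
# spacings stay strictly positive.
threshold_nnsd <- function(r, threshold, smoothing_df = 10) {
  m <- r
  m[abs(m) < threshold] <- 0
  diag(m) <- 1
  connected <- rowSums(abs(m) >= threshold) > 1  # beyond the diagonal
  m <- m[connected, connected, drop = FALSE]
  if (nrow(m) < 20) abort("fewer than 20 connected taxa at threshold %.2f",
                          threshold)
  eigs <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  eigs <- sort(eigs)
  eigs <- eigs[c(TRUE, diff(eigs) > 1e-10)]  # collapse degeneracies
  unfolded <- unfold_eigenvalues(eigs, smoothing_df)
  spacings <- diff(unfolded)
  spacings <- spacings[spacings > 0]
  nnsd_fit(spacings)
}

#' Scan correlation thresholds for the RMT Poisson transition
#'
#' For each threshold in the grid, entries with |r| below the threshold
#' are zeroed, the eigenvalue spectrum of the surviving matrix is unfolded
#' and its NNSD is tested against the Poisson and GOE laws. The selected
#' threshold is the smallest grid value whose NNSD conforms to Poisson
#' statistics (p_poisson > alpha): at that point random (GOE-like) noise
#' structure has been removed and only nonrandom co-occurrence remains.
#'
#' @param c a [correlation_matrix()].
#' @param grid increasing thresholds in (0, 1); default `seq(0.30, 0.95,
#'   0.01)`.
#' @param alpha Poisson-conformity level (default 0.05).
#' @param smoothing_df unfolding spline degrees of freedom.
#' @return List of class `rmt_scan`: `scan` (data.frame with one row per
#'   evaluable threshold: `threshold`, `n_kept_eigenvalues`,
#'   `chi2_poisson`, `p_poisson`, `chi2_goe`, `p_goe`) and
#'   `selected_threshold`.
#' @export
select_rmt_threshold <- function(c, grid = seq(0.30, 0.95, by = 0.01),
                                 alpha = 0.05, smoothing_df = 10) {
  stopifnot(inherits(c, "correlation_matrix"))
  if (any(grid <= 0) || any(grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly increasing within (0, 1)")
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch(threshold_nnsd(c$r, grid[i], smoothing_df),
                    error = function(e) NULL)
    rows[[i]] <- if (is.null(res)) {
      data.frame(threshold = grid[i], n_kept_eigenvalues = NA_integer_,
                 chi2_poisson = NA_real_, p_poisson = NA_real_,
                 chi2_goe = NA_real_, p_goe = NA_real_)
    } else {
      data.frame(threshold = grid[i], n_kept_eigenvalues = res$n + 1L,
                 chi2_poisson = res$chi2_poisson, p_poisson = res$p_poisson,
                 chi2_goe = res$chi2_goe, p_goe = res$p_goe)
    }
  }
  scan <- do.call(rbind, rows)
  ok <- !is.na(scan$p_poisson) & scan$p_poisson > alpha
  if (!any(ok)) {
    e <- structure(class = c("rmt_no_threshold", "error", "condition"),
                   list(message = "no threshold reaches Poisson conformity",
                        call = sys.call(), scan = scan))
    stop(e)
  }
  structure(list(scan = scan, selected_threshold = grid[which(ok)[1]],
                 alpha = alpha),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("rmt_scan: %d thresholds, selected %.2f (alpha %.2f)\n",
              nrow(x$scan), x$selected_threshold, x$alpha))
  invisible(x)
}

#' Build a signed co-occurrence network at a correlation threshold
#'
#' Keeps an edge for every taxon pair with |r| >= threshold (ties at the
#' boundary included), signed by the correlation sign; isolated taxa are
#' dropped. Node annotations (lineage, mean relative abundance) are
#' attached for export; abundance is visualization metadata only.
#'
#' @param c a [correlation_matrix()].
#' @param threshold correlation cutoff in (0, 1).
#' @param taxonomy optional [taxonomy_map()] for node lineages.
#' @param abundances optional [rel_abund_table()] for node mean abundances
#'   (defaults to the abundances recorded in `c`).
#' @return List of class `signed_network`: `graph` (igraph, edge
#'   attributes `r`, `sign`; vertex attributes `abundance`, `phylum`),
#'   `threshold`, `n_nodes`, `n_edges`.
#' @export
build_network <- function(c, threshold, taxonomy = NULL, abundances = NULL) {
  stopifnot(inherits(c, "correlation_matrix"))
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  r <- c$r
  adj <- abs(r) >= threshold
  diag(adj) <- FALSE
  keep <- rowSums(adj) > 0
  if (!any(adj)) abort("empty edge set at threshold %.2f", threshold)
  adj <- adj[keep, keep, drop = FALSE]
  r <- r[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ends <- igraph::as_edgelist(g, names = TRUE)
  rvals <- r[cbind(ends[, 1], ends[, 2])]
  igraph::E(g)$r <- rvals
  igraph::E(g)$sign <- ifelse(rvals >= 0, "+", "-")
  ab <- if (!is.null(abundances)) {
    rowMeans(abundances$abund)[igraph::V(g)$name]
  } else {
    c$abundance[igraph::V(g)$name]
  }
  igraph::V(g)$abundance <- unname(ab)
  if (!is.null(taxonomy)) {
    lin <- taxonomy[match(igraph::V(g)$name, taxonomy$feature_id), ]
    igraph::V(g)$phylum <- as.character(lin$phylum)
  }
  structure(list(graph = g, threshold = threshold,
                 n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "signed_network: %d nodes, %d edges (%d +, %d -) at threshold %.2f\n",
    x$n_nodes, x$n_edges, sum(igraph::E(x$graph)$sign == "+"),
    sum(igraph::E(x$graph)$sign == "-"), x$threshold))
  invisible(x)
}

#' Export a signed network as an edge-list TSV (and optionally GraphML)
#'
#' @param g a [build_network()] result.
#' @param path destination TSV (columns node_a, node_b, r, sign).
#' @param graphml_path optional GraphML destination for external
#'   visualization tools.
#' @export
write_network <- function(g, path, graphml_path = NULL) {
  stopifnot(inherits(g, "signed_network"))
  ends <- igraph::as_edgelist(g$graph, names = TRUE)
  df <- data.frame(node_a = ends[, 1], node_b = ends[, 2],
                   r = igraph::E(g$graph)$r, sign = igraph::E(g$graph)$sign)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g$graph, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' Topology indices of a co-occurrence network
#'
#' Computes, on the unsigned graph: average degree (2E/N), global
#' transitivity (3 triangles / connected triples), geodesic efficiency
#' (mean over ordered node pairs of 1/shortest-path length, 0 for
#' unreachable pairs), harmonic geodesic distance (its reciprocal), and
#' Newman-Girvan modularity of a deterministic greedy (fast-greedy)
#' partition together with its module count.
#'
#' @param g a [build_network()] result with at least 3 nodes.
#' @return List of class `network_topology`: `total_nodes`, `total_links`,
#'   `avgK`, `transitivity`, `geodesic_efficiency`,
#'   `harmonic_geodesic_distance`, `modularity`, `n_modules`,
#'   `unreachable_convention`.
#' @export
topology_metrics <- function(g) {
  stopifnot(inherits(g, "signed_network"))
  gr <- g$graph
  n <- igraph::vcount(gr)
  if (n < 3) abort("need at least 3 nodes")
  e <- igraph::ecount(gr)
  trans <- igraph::transitivity(gr, type = "global")
  if (is.nan(trans)) trans <- 0
  sp <- igraph::distances(gr)
  inv <- 1 / sp[row(sp) != col(sp)]  # Inf distances contribute 0
  inv[!is.finite(inv)] <- 0
  eff <- mean(inv)
  comm <- igraph::cluster_fast_greedy(igraph::simplify(gr))
  structure(list(total_nodes = n, total_links = e, avgK = 2 * e / n,
                 transitivity = trans, geodesic_efficiency = eff,
                 harmonic_geodesic_distance = 1 / eff,
                 modularity = igraph::modularity(comm),
                 n_modules = length(comm),
                 membership = igraph::membership(comm),
                 unreachable_convention = "zero efficiency contribution"),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0(
    "network_topology: %d nodes, %d links, avgK %.3f, transitivity %.3f,\n",
    "  efficiency %.3f (harmonic distance %.3f), modularity %.3f ",
    "(%d modules)\n"),
    x$total_nodes, x$total_links, x$avgK, x$transitivity,
    x$geodesic_efficiency, x$harmonic_geodesic_distance, x$modularity,
    x$n_modules))
  invisible(x)
}

#' Count links between a focal lineage and all other members
#'
#' Tallies edges with exactly one endpoint in the focal group (e.g. links
#' between Actinobacteria and other phyla), split by correlation sign,
#' and their fractions of all network links.
#'
#' @param g a [build_network()] result whose nodes carry a `phylum`
#'   attribute (or supply `taxonomy`).
#' @param focal_lineage named character vector, e.g.
#'   `c(phylum = "Actinobacteria")`.
#' @param taxonomy optional [taxonomy_map()] if the graph lacks lineage
#'   annotations.
#' @return List of class `link_accounting`: `focal`, `total_links`,
#'   `focal_links`, `focal_pos`, `focal_neg` and the corresponding
#'   `frac_*` fractions of total links.
#' @export
intergroup_links <- function(g, focal_lineage, taxonomy = NULL) {
  stopifnot(inherits(g, "signed_network"))
  gr <- g$graph
  nodes <- igraph::V(gr)$name
  rank <- names(focal_lineage)[1]
  label <- focal_lineage[[1]]
  node_label <- if (!is.null(taxonomy)) {
    as.character(taxonomy[match(nodes, taxonomy$feature_id), rank])
  } else if (rank == "phylum" && !is.null(igraph::vertex_attr(gr, "phylum"))) {
    igraph::V(gr)$phylum
  } else {
    abort("graph has no '%s' annotation; supply a taxonomy map", rank)
  }
  focal_nodes <- nodes[!is.na(node_label) & node_label == label]
  if (length(focal_nodes) == 0) abort("no node in focal lineage '%s'", label)
  ends <- igraph::as_edgelist(gr, names = TRUE)
  in_a <- ends[, 1] %in% focal_nodes
  in_b <- ends[, 2] %in% focal_nodes
  mixed <- xor(in_a, in_b)
  signs <- igraph::E(gr)$sign
  total <- igraph::ecount(gr)
  fl <- sum(mixed)
  fp <- sum(mixed & signs == "+")
  fn <- sum(mixed & signs == "-")
  structure(list(focal = label, total_links = total,
                 focal_links = fl, focal_pos = fp, focal_neg = fn,
                 frac_links = fl / total, frac_pos = fp / total,
                 frac_neg = fn / total),
            class = "link_accounting")
}

#' @export
print.link_accounting <- function(x, ...) {
  cat(sprintf(paste0(
    "link_accounting (%s): %d of %d links mixed (%.1f%%); ",
    "+%d (%.1f%%), -%d (%.1f%%)\n"),
    x$focal, x$focal_links, x$total_links, 100 * x$frac_links,
    x$focal_pos, 100 * x$frac_pos, x$focal_neg, 100 * x$frac_neg))
  invisible(x)
}
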