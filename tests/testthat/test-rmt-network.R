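# Correlation matrices, spectral unfolding, NNSD fits, RMT threshold
# selection, network construction, topology and link accounting.

test_that("correlation matrices honor the prevalence filter", {
  withr::with_seed(81, {
    base <- matrix(rlnorm(10 * 12), 10, 12,
                   dimnames = list(paste0("t", 1:10), paste0("s", 1:12)))
    base[1, ] <- 2 * base[2, ]          # proportional pair
    base[10, sample(12, 8)] <- 0        # present in only 4 of 12 samples
    rel <- rel_abund_table(sweep(base, 2, colSums(base), "/"))
    cm <- correlation_matrix(rel, min_prevalence = 0.5)
    expect_false("t10" %in% rownames(cm$r))
    # closure perturbs proportionality only at the 1e-2 level; check the
    # raw profiles against a naive double-loop oracle instead
    naive <- matrix(0, nrow(cm$r), ncol(cm$r), dimnames = dimnames(cm$r))
    kept <- rel$abund[rownames(cm$r), ]
    for (i in seq_len(nrow(naive))) {
      for (j in seq_len(nrow(naive))) {
        naive[i, j] <- cor(kept[i, ], kept[j, ])
      }
    }
    expect_lt(max(abs(cm$r - naive)), 1e-12)
  })
  t <- fixture_count_table(n_taxa = 6, n_samples = 4)
  expect_error(correlation_matrix(to_relative_abundance(t)),
               "at least 8 samples")
})

test_that("perfectly proportional profiles correlate at one", {
  m <- matrix(rlnorm(24, sdlog = 0.2), 2, 12,
              dimnames = list(c("a", "b"), paste0("s", 1:12)))
  m[2, ] <- 3 * m[1, ]
  rel <- structure(list(abund = m, provenance = "raw"),
                   class = "rel_abund_table")
  cm <- correlation_matrix(rel, min_prevalence = 0.5)
  expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
})

test_that("unfolding yields unit mean spacing and preserves order", {
  # equally spaced eigenvalues unfold to unit spacings
  u <- unfold_eigenvalues(seq(0, 10, length.out = 50))
  sp <- diff(u)
  expect_true(all(abs(sp - 1) < 0.1))
  expect_equal(mean(sp), 1, tolerance = 0.05)
  expect_false(is.unsorted(u))

  withr::with_seed(82, {
    for (k in 1:5) {
      m <- matrix(rnorm(40 * 40), 40)
      eigs <- eigen((m + t(m)) / sqrt(2), symmetric = TRUE,
                    only.values = TRUE)$values
      uu <- unfold_eigenvalues(eigs)
      expect_equal(mean(diff(uu)), 1, tolerance = 0.05)
      expect_false(is.unsorted(uu))
    }
  })
  expect_error(unfold_eigenvalues(rep(1, 30)), "degenerate")
  expect_error(unfold_eigenvalues(1:10), "at least 20")
})

test_that("NNSD fits separate Poisson from Wigner spacings", {
  withr::with_seed(83, {
    pois <- nnsd_fit(rexp(500))
    expect_gt(pois$p_poisson, 0.05)
    expect_lt(pois$p_goe, 0.05)
    goe <- nnsd_fit(sqrt(-4 * log(1 - runif(500)) / pi))
    expect_gt(goe$p_goe, 0.05)
    expect_lt(goe$p_poisson, 0.05)
  })
  cst <- nnsd_fit(rep(1, 100))
  expect_lt(cst$p_poisson, 0.05)
  expect_lt(cst$p_goe, 0.05)
  expect_error(nnsd_fit(c(rep(1, 40), 0)), "strictly positive")
  expect_error(nnsd_fit(rep(1, 10)), "at least 30")
})

test_that("threshold selection finds the noise-block transition", {
  tr <- simulation_truth(seed = 84, focal_mixed_pos = 0L,
                         focal_mixed_neg = 0L)
  o <- simulate_correlated_otus(tr, n_samples = 800)
  cm <- correlation_matrix(o$abund)
  scan <- select_rmt_threshold(cm)
  expect_gt(scan$selected_threshold, 0.2)
  expect_lt(scan$selected_threshold, 0.8)
  expect_true(scan$selected_threshold %in% scan$scan$threshold)
  # a one-point grid containing a qualifying threshold returns it
  one <- select_rmt_threshold(cm, grid = scan$selected_threshold)
  expect_equal(one$selected_threshold, scan$selected_threshold)
})

test_that("independent profiles conform to Poisson at low thresholds", {
  withr::with_seed(85, {
    m <- matrix(rlnorm(60 * 30, sdlog = 0.3), 60, 30,
                dimnames = list(sprintf("t%02d", 1:60),
                                sprintf("s%02d", 1:30)))
    rel <- rel_abund_table(sweep(m, 2, colSums(m), "/"))
    cm <- correlation_matrix(rel, min_prevalence = 0.5)
    sel <- tryCatch(select_rmt_threshold(cm)$selected_threshold,
                    error = function(e) e)
    if (is.numeric(sel)) {
      expect_lte(sel, 0.45)
    } else {
      # no threshold qualified: the error must carry the full scan
      expect_s3_class(sel, "rmt_no_threshold")
      expect_true(is.data.frame(sel$scan))
    }
  })
})

test_that("network construction filters edges exactly at the threshold", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- -0.9
  r[2, 3] <- r[3, 2] <- 0.1
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- build_network(hand_correlation(r), 0.8)
  expect_equal(net$n_edges, 2L)
  expect_setequal(igraph::E(net$graph)$sign, c("+", "-"))

  withr::with_seed(86, {
    rr <- matrix(runif(20 * 20, -1, 1), 20)
    rr <- (rr + t(rr)) / 2
    diag(rr) <- 1
    dimnames(rr) <- list(paste0("t", 1:20), paste0("t", 1:20))
    prev <- Inf
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      n_br <- sum(abs(rr[upper.tri(rr)]) >= thr)
      if (n_br == 0) break
      net_t <- build_network(hand_correlation(rr), thr)
      expect_equal(net_t$n_edges, n_br)        # brute-force filter
      expect_lte(net_t$n_edges, prev)          # monotone in threshold
      prev <- net_t$n_edges
    }
  })
  expect_error(build_network(hand_correlation(diag(3)), 0.5), "empty edge")
})

test_that("topology indices match closed forms on canonical graphs", {
  tri <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tri[upper.tri(tri)] <- 0.9
  tri <- tri + t(tri)
  net <- network_from_adjacency(tri, 0.5)
  topo <- topology_metrics(net)
  expect_equal(topo$avgK, 2)
  expect_equal(topo$transitivity, 1)
  expect_equal(topo$geodesic_efficiency, 1)
  expect_equal(topo$harmonic_geodesic_distance, 1)

  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- 0.9
  path["b", "c"] <- path["c", "b"] <- 0.9
  tp <- topology_metrics(network_from_adjacency(path, 0.5))
  expect_equal(tp$transitivity, 0)
  expect_equal(tp$geodesic_efficiency, 5 / 6)
  expect_equal(tp$harmonic_geodesic_distance, 6 / 5)
  expect_equal(tp$avgK, 2 * tp$total_links / tp$total_nodes)

  # relabeling nodes changes nothing
  perm <- c("c", "a", "b")
  tp2 <- topology_metrics(network_from_adjacency(path[perm, perm], 0.5))
  expect_equal(tp2$transitivity, tp$transitivity)
  expect_equal(tp2$geodesic_efficiency, tp$geodesic_efficiency)
})

test_that("two disjoint cliques are recovered as two modules with Q = 0.5", {
  n <- 20
  adj <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  adj[1:10, 1:10] <- 0.9
  adj[11:20, 11:20] <- 0.9
  diag(adj) <- 0
  topo <- topology_metrics(network_from_adjacency(adj, 0.5))
  # planted partition Q: 2 * (1/2 - 1/4) = 0.5 exactly
  expect_equal(topo$modularity, 0.5, tolerance = 1e-12)
  expect_gt(topo$modularity, 0.4)
  expect_equal(topo$n_modules, 2L)
  expect_gte(topo$modularity, 0)  # >= trivial one-module partition
})

test_that("link accounting counts mixed edges by sign", {
  # star: focal center, four non-focal leaves with signs + + - -
  r <- diag(5)
  dimnames(r) <- list(c("f", "o1", "o2", "o3", "o4"),
                      c("f", "o1", "o2", "o3", "o4"))
  r["f", "o1"] <- r["o1", "f"] <- 0.9
  r["f", "o2"] <- r["o2", "f"] <- 0.85
  r["f", "o3"] <- r["o3", "f"] <- -0.9
  r["f", "o4"] <- r["o4", "f"] <- -0.85
  net <- build_network(hand_correlation(r), 0.8,
                       taxonomy = fixture_taxonomy(
                         c("f", "o1", "o2", "o3", "o4"),
                         c("Actinobacteria", rep("Other", 4))))
  la <- intergroup_links(net, c(phylum = "Actinobacteria"))
  expect_equal(la$focal_links, 4L)
  expect_equal(la$total_links, 4L)
  expect_equal(la$focal_pos, 2L)
  expect_equal(la$frac_pos, 0.5)
  expect_equal(la$focal_pos + la$focal_neg, la$focal_links)

  # with every node focal there are no mixed edges
  net_all <- build_network(hand_correlation(r), 0.8,
                           taxonomy = fixture_taxonomy(
                             c("f", "o1", "o2", "o3", "o4"),
                             rep("Actinobacteria", 5)))
  expect_equal(intergroup_links(net_all,
                                c(phylum = "Actinobacteria"))$focal_links,
               0L)
  expect_error(intergroup_links(net, c(phylum = "Firmicutes")), "no node")
})

test_that("mixed-edge fractions on random two-group graphs match theory", {
  # Erdos-Renyi edges with random labels: a fraction 2 p (1 - p) of edges
  # is expected to be mixed
  withr::with_seed(87, {
    n <- 40
    p_focal <- 0.3
    fracs <- replicate(30, {
      adj <- matrix(0, n, n)
      adj[upper.tri(adj)] <- ifelse(runif(n * (n - 1) / 2) < 0.3, 0.9, 0)
      adj <- adj + t(adj)
      dimnames(adj) <- list(paste0("t", 1:n), paste0("t", 1:n))
      lab <- ifelse(runif(n) < p_focal, "Actinobacteria", "Other")
      net <- build_network(hand_correlation(adj), 0.5,
                           taxonomy = fixture_taxonomy(paste0("t", 1:n),
                                                       lab))
      intergroup_links(net, c(phylum = "Actinobacteria"))$frac_links
    })
    expected <- 2 * p_focal * (1 - p_focal)
    se <- sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - expected), 3 * se + 0.02)
  })
})
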