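# End-to-end orchestration: chemistry distances -> per-phylum distance
# decay and focal contrasts -> RMT co-occurrence network and link
# accounting -> CAZyme attribution, variation and fertility contrasts.

#' Run the full analysis pipeline on a study bundle
#'
#' Executes every stage of the straw-decomposition inference chain on a
#' (synthetic or real) study bundle: standardized chemistry Euclidean
#' distances; rarefaction and relative abundances; per-phylum renormalized
#' subsets with distance-decay fits and focal-group slope contrasts; the
#' RMT-thresholded signed co-occurrence network with topology indices and
#' focal link accounting; and CAZyme profiles, average-CAZyme ratios,
#' stage-variation profiles and fertility contrasts.
#'
#' @param bundle a [simulate_study()] result (or an equivalent list built
#'   from read-in tables).
#' @param n_perm permutations for every permutation test (default 999).
#' @param seed integer seed for all stochastic stages (default: the
#'   bundle's truth seed).
#' @param scheme slope-contrast permutation scheme (see
#'   [slope_contrast_test()]).
#' @param grid RMT threshold grid.
#' @param alpha Poisson-conformity level for threshold selection.
#' @return List of class `study_results` with components `slopes`
#'   ([slope_panel()]), `mantel` (chemistry vs whole community),
#'   `permanova` (stages), `rmt` ([select_rmt_threshold()]), `network`,
#'   `topology`, `links`, `cazyme_profile`, `cazyme_ratio`, `variation`,
#'   `fertility`.
#' @export
run_study_pipeline <- function(bundle, n_perm = 999,
                               seed = bundle$truth$seed,
                               scheme = c("taxon_shuffle", "sample_swap",
                                          "pair_label"),
                               grid = seq(0.30, 0.95, by = 0.01),
                               alpha = 0.05) {
  scheme <- match.arg(scheme)
  truth <- bundle$truth
  focal <- truth$focal_phylum
  chem_d <- chemistry_distance(bundle$chemistry, standardize = TRUE)

  counts <- rarefy(bundle$counts, min(colSums(bundle$counts$counts)),
                   seed = seed)
  rel <- to_relative_abundance(counts)
  phyla <- sort(unique(bundle$taxonomy$phylum))
  tables <- lapply(phyla, function(p) {
    subset_by_lineage(rel, bundle$taxonomy, c(phylum = p),
                      renormalize = TRUE)
  })
  names(tables) <- phyla
  slopes <- slope_panel(chem_d, tables, focal = focal, n_perm = n_perm,
                        seed = seed, scheme = scheme,
                        alternative = "two_sided")
  comm_d <- bray_curtis(rel)
  mant <- mantel_test(chem_d, comm_d, n_perm = n_perm, seed = seed + 11L)
  perma <- permanova(comm_d, counts$sample_meta$stage_weeks,
                     n_perm = n_perm, seed = seed + 12L)

  cmat <- correlation_matrix(bundle$otus$abund, min_prevalence = 0.5)
  rmt <- select_rmt_threshold(cmat, grid = grid, alpha = alpha)
  net <- build_network(cmat, rmt$selected_threshold,
                       taxonomy = bundle$otus$taxonomy)
  topo <- topology_metrics(net)
  links <- intergroup_links(net, c(phylum = focal))

  genes <- rpkm_normalize(bundle$genes)
  prof <- phylum_cazyme_profile(genes, names(truth$phylum_weight),
                                denominator = "table", by = "pooled")
  caz_share <- rowSums(prof$shares)
  phy_rel <- aggregate_by_rank(rel, bundle$taxonomy, "phylum")
  taxa_share <- rowMeans(phy_rel$abund)[names(caz_share)]
  taxa_share <- taxa_share / sum(taxa_share)
  ratio <- average_cazyme_ratio(caz_share, taxa_share)
  prof_stage <- phylum_cazyme_profile(genes, names(truth$phylum_weight),
                                      denominator = "class", by = "stage")
  varp <- variation_profile(prof_stage)
  class_by_sample <- phylum_cazyme_profile(genes, names(truth$phylum_weight),
                                           denominator = "table",
                                           by = "sample")
  focal_mat <- class_by_sample$shares[focal, , ]
  focal_mat <- rbind(total = colSums(focal_mat), focal_mat)
  fert <- fertility_contrast(focal_mat,
                             genes$sample_meta$fertility)

  structure(list(slopes = slopes, mantel = mant, permanova = perma,
                 rmt = rmt, network = net, topology = topo, links = links,
                 cazyme_profile = prof, cazyme_ratio = ratio,
                 variation = varp, fertility = fert,
                 focal = focal, seed = as.integer(seed),
                 n_perm = as.integer(n_perm)),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("study_results\n-------------\n")
  print(x$slopes)
  cat(sprintf("Mantel chemistry~community: r %.3f, p %.4g\n",
              x$mantel$r, x$mantel$p))
  cat(sprintf("PERMANOVA stages: pseudo-F %.3f, p %.4g\n",
              x$permanova$pseudo_F, x$permanova$p))
  print(x$rmt)
  print(x$topology)
  print(x$links)
  cat("average-CAZyme ratio per phylum:\n")
  print(round(x$cazyme_ratio, 3))
  print(x$variation)
  cat("fertility contrast (focal phylum):\n")
  print(x$fertility)
  invisible(x)
}

#' Flatten pipeline results to a named list of numbers
#'
#' Used for JSON export and for bit-identity checks between runs.
#'
#' @param res a [run_study_pipeline()] result.
#' @return Named list of scalars and small named vectors.
#' @export
summarize_results <- function(res) {
  stopifnot(inherits(res, "study_results"))
  fits <- res$slopes$fits
  contrasts <- res$slopes$contrasts
  out <- list(
    focal = res$focal,
    slopes = lapply(fits, function(f) {
      list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
           p_slope = f$p_slope)
    }),
    contrasts = lapply(contrasts, function(ct) {
      list(delta = ct$delta, p = ct$p_perm)
    }),
    mantel = list(r = res$mantel$r, p = res$mantel$p),
    permanova = list(pseudo_F = res$permanova$pseudo_F, p = res$permanova$p),
    rmt_threshold = res$rmt$selected_threshold,
    topology = res$topology[c("total_nodes", "total_links", "avgK",
                              "transitivity", "geodesic_efficiency",
                              "harmonic_geodesic_distance", "modularity",
                              "n_modules")],
    links = res$links[c("total_links", "focal_links", "focal_pos",
                        "focal_neg", "frac_links", "frac_pos", "frac_neg")],
    cazyme_ratio = as.list(res$cazyme_ratio),
    mean_variation = as.list(res$variation$mean_variation),
    fertility = lapply(seq_len(nrow(res$fertility)), function(i) {
      as.list(res$fertility[i, c("feature", "mean_high", "mean_low",
                                 "p_value")])
    })
  )
  out
}

#' Write pipeline results as JSON
#'
#' @param res a [run_study_pipeline()] result.
#' @param path destination JSON file.
#' @export
write_results_json <- function(res, path) {
  jsonlite::write_json(summarize_results(res), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
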