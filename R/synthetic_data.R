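# Synthetic study generator with known ground truth. Emulates the derived
# tables of a three-site straw-decomposition field/SIP study: declining
# straw-chemistry trajectories, phylum communities whose distance-decay
# steepness is planted through Gaussian niche breadths, block-correlated
# OTU profiles with planted modules and focal mixed links, and
# taxon-annotated CAZyme gene tables with a planted fertility effect.

#' Ground-truth parameter set for the synthetic study
#'
#' Collects every generator parameter in one serializable object, so any
#' dataset can be regenerated bit-identically from (truth, seed) and
#' recovery tests can compare estimates against the planted values.
#'
#' Defaults mirror the emulated field design: 3 sites (CS fertile, YT less
#' fertile, CQ unclassified), stages 1, 2, 4, 8 and 16 weeks, 12
#' replicates and a rarefaction-scale depth of 8000 reads, with five
#' dominant phyla whose niche breadths make Actinobacteria and
#' Acidobacteria the flat (stable) groups.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default component (see the returned list).
#' @return List of class `simulation_truth`.
#' @export
simulation_truth <- function(seed = 1, ...) {
  truth <- list(
    seed = as.integer(seed),
    sites = c("CQ", "CS", "YT"),
    site_fertility = c(CQ = NA, CS = "high", YT = "low"),
    stages = c(1, 2, 4, 8, 16),
    reps = 12L,
    depth = 8000L,
    # chemistry: initial mass fractions and per-week exponential decay
    chem_initial = c(cellulose = 0.38, hemicellulose = 0.30,
                     lignin = 0.18, wsp = 0.08),
    chem_decay = c(cellulose = 0.060, hemicellulose = 0.070,
                   lignin = 0.012, wsp = 0.120),
    site_rate_multiplier = c(CQ = 0.9, CS = 1.1, YT = 0.8),
    chem_noise_sdlog = 0.05,
    # communities: Gaussian niche response on the chemistry gradient;
    # larger sigma = broader niche = flatter distance decay
    groups = c(Acidobacteria = 2.2, Actinobacteria = 2.0,
               Bacteroidetes = 0.8, Firmicutes = 0.9,
               Proteobacteria = 1.0),
    # expected whole-community abundance share per group: the focal
    # Actinobacteria stay non-dominant (a few percent of reads) even
    # though they carry a large share of the CAZyme pool
    group_abundance = c(Acidobacteria = 0.12, Actinobacteria = 0.046,
                        Bacteroidetes = 0.20, Firmicutes = 0.28,
                        Proteobacteria = 0.354),
    n_taxa_per_group = 40L,
    # correlated OTUs for the co-occurrence branch
    modules = c(12L, 12L, 12L, 12L, 12L),
    within_r = 0.8,
    focal_phylum = "Actinobacteria",
    focal_module = 5L,
    focal_mixed_pos = 10L,
    focal_mixed_neg = 20L,
    mixed_r = 0.9,
    otu_n_samples = 60L,
    # gene tables
    cazy_alpha = c(GH = 0.30, GT = 0.25, CE = 0.15, CBM = 0.15,
                   PL = 0.05, AA = 0.10),
    phylum_weight = c(Acidobacteria = 0.13, Actinobacteria = 0.15,
                      Bacteroidetes = 0.24, Firmicutes = 0.25,
                      Proteobacteria = 0.23),
    genes_per_class = 6L,
    gene_length_range = c(300, 3000),
    reads_per_sample = 1e6,
    nb_dispersion = 0.3,
    sample_noise_sdlog = 0.1,
    fertility_fold = 2,
    fertility_classes = c("GH", "GT", "CE"),
    n_samples_per_class = 6L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(truth))
  if (length(unknown) > 0) {
    abort("unknown truth parameter(s): %s", paste(unknown, collapse = ", "))
  }
  truth[names(dots)] <- dots
  structure(truth, class = "simulation_truth")
}

#' Serialize / restore a ground-truth object as JSON
#'
#' @param truth a [simulation_truth()].
#' @param path destination/source JSON file.
#' @name truth_io
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors go out as JSON objects so their names survive
  enc <- lapply(unclass(truth), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname truth_io
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(x) {
    if (is.list(x)) {
      # restore named vectors; JSON null (dropped by unlist) becomes NA
      unlist(lapply(x, function(v) if (is.null(v)) NA else v))
    } else {
      x
    }
  })
  do.call(simulation_truth, c(list(seed = raw$seed),
                              raw[setdiff(names(raw), "seed")]))
}

study_sample_meta <- function(truth, sites = truth$sites,
                              stages = truth$stages, reps = truth$reps) {
  grid <- expand.grid(replicate = seq_len(reps), stage_weeks = stages,
                      site = sites, stringsAsFactors = FALSE)
  grid <- grid[, c("site", "stage_weeks", "replicate")]
  data.frame(
    sample_id = sprintf("%s_w%02d_r%02d", grid$site, grid$stage_weeks,
                        grid$replicate),
    site = grid$site, stage_weeks = grid$stage_weeks,
    replicate = grid$replicate,
    fertility = unname(truth$site_fertility[grid$site]),
    stringsAsFactors = FALSE)
}

#' Simulate straw chemistry trajectories
#'
#' Each of the four components decays exponentially with decomposition
#' stage at a site-specific rate, with multiplicative lognormal replicate
#' noise; all values stay within (0, 1).
#'
#' @param truth a [simulation_truth()].
#' @param sites,stages,reps design overrides (defaults from `truth`).
#' @param seed integer seed (defaults to `truth$seed`).
#' @return A [chemistry_table()] with the study sample metadata attached
#'   as attribute `"sample_meta"`.
#' @export
simulate_chemistry <- function(truth = simulation_truth(),
                               sites = truth$sites, stages = truth$stages,
                               reps = truth$reps, seed = truth$seed) {
  if (is.unsorted(stages, strictly = TRUE)) {
    abort("stages must be strictly increasing")
  }
  meta <- study_sample_meta(truth, sites, stages, reps)
  n <- nrow(meta)
  comp <- with_seed(seed, {
    out <- matrix(0, n, length(CHEMISTRY_COMPONENTS),
                  dimnames = list(meta$sample_id, CHEMISTRY_COMPONENTS))
    for (k in CHEMISTRY_COMPONENTS) {
      rate <- truth$chem_decay[[k]] *
        truth$site_rate_multiplier[meta$site]
      mean_val <- truth$chem_initial[[k]] * exp(-rate * meta$stage_weeks)
      noise <- if (truth$chem_noise_sdlog > 0) {
        rlnorm(n, meanlog = -truth$chem_noise_sdlog^2 / 2,
               sdlog = truth$chem_noise_sdlog)
      } else {
        rep(1, n)
      }
      out[, k] <- pmin(pmax(mean_val * noise, 1e-6), 1 - 1e-6)
    }
    out
  })
  chem <- chemistry_table(data.frame(sample_id = meta$sample_id, comp,
                                     check.names = FALSE))
  attr(chem, "sample_meta") <- meta
  chem
}

# First principal coordinate of the standardized chemistry components:
# the latent decomposition gradient on which niche responses are placed.
chemistry_gradient <- function(chem) {
  comp <- scale(as.matrix(as.data.frame(chem)[, CHEMISTRY_COMPONENTS]))
  pc <- prcomp(comp, center = FALSE, scale. = FALSE)
  z <- pc$x[, 1]
  names(z) <- chem$sample_id
  z
}

#' Simulate phylum communities with planted distance-decay steepness
#'
#' Places every sample on a latent gradient (the first principal
#' coordinate of its standardized chemistry) and gives each taxon of group
#' g a Gaussian response curve with niche breadth sigma_g on that
#' gradient. Narrow niches turn over fast along the gradient and produce a
#' steep (more negative) distance-decay slope; the planted ordering of the
#' sigmas therefore maps to a planted ordering of slopes. Counts are
#' multinomial at the configured depth.
#'
#' @param chem a [simulate_chemistry()] result (carries sample metadata).
#' @param truth a [simulation_truth()]; `truth$groups` is the named vector
#'   of niche breadths (all > 0; `Inf` allowed for a gradient-blind
#'   group).
#' @param seed integer seed (defaults to `truth$seed`).
#' @return List with `counts` (a [count_table()]) and `taxonomy` (a
#'   [taxonomy_map()] assigning each OTU its group as phylum).
#' @export
simulate_communities <- function(chem, truth = simulation_truth(),
                                 seed = truth$seed) {
  sigmas <- truth$groups
  if (any(sigmas <= 0)) abort("niche breadths must be > 0")
  meta <- attr(chem, "sample_meta")
  if (is.null(meta)) abort("chemistry table lacks the sample_meta attribute")
  z <- chemistry_gradient(chem)
  n_s <- length(z)
  k <- truth$n_taxa_per_group
  res <- with_seed(seed, {
    span <- range(z)
    pad <- 0.25 * diff(span)
    # planted whole-community share per group; equal shares when the
    # truth's share table does not cover these groups
    shares <- truth$group_abundance[names(sigmas)]
    if (anyNA(shares)) shares <- rep(1 / length(sigmas), length(sigmas))
    shares <- shares / sum(shares)
    expected <- NULL
    ids <- character(0)
    phyla <- character(0)
    for (gi in seq_along(sigmas)) {
      g <- names(sigmas)[gi]
      mu <- runif(k, span[1] - pad, span[2] + pad)
      base <- rlnorm(k, 0, 1)
      resp <- if (is.finite(sigmas[[g]])) {
        exp(-outer(mu, z, "-")^2 / (2 * sigmas[[g]]^2))
      } else {
        matrix(1, k, n_s)
      }
      block <- base * resp
      block <- block * (shares[gi] / mean(colSums(block)))
      expected <- rbind(expected, block)
      ids <- c(ids, sprintf("OTU_%s_%03d", g, seq_len(k)))
      phyla <- c(phyla, rep(g, k))
    }
    rownames(expected) <- ids
    colnames(expected) <- names(z)
    counts <- vapply(seq_len(n_s), function(j) {
      p <- expected[, j] / sum(expected[, j])
      rmultinom(1, truth$depth, p)[, 1]
    }, integer(nrow(expected)))
    dimnames(counts) <- dimnames(expected)
    list(counts = counts, phyla = phyla, ids = ids)
  })
  tax <- taxonomy_map(data.frame(feature_id = res$ids, domain = "Bacteria",
                                 phylum = res$phyla))
  list(counts = count_table(res$counts, meta), taxonomy = tax)
}

#' Simulate block-correlated OTU profiles with planted focal links
#'
#' Draws a latent Gaussian with block covariance (correlation `within_r`
#' inside each planted module, none between), maps it to non-negative
#' abundances through a monotone exponential transform, and closes samples
#' to relative abundances. One module is labeled as the focal phylum; a
#' configured number of non-focal taxa are rewired to correlate at
#' `+/- mixed_r` with focal partners, planting positive and negative
#' mixed links for the network link-accounting stage.
#'
#' @param truth a [simulation_truth()]; uses `modules`, `within_r`,
#'   `focal_module`, `focal_mixed_pos`, `focal_mixed_neg`, `mixed_r`,
#'   `otu_n_samples`.
#' @param n_samples number of samples (default `truth$otu_n_samples`).
#' @param seed integer seed (defaults to `truth$seed`).
#' @return List with `abund` (a [rel_abund_table()]), `taxonomy` (a
#'   [taxonomy_map()]), `module` (planted module id per taxon) and
#'   `mixed_pairs` (data.frame of the rewired focal/non-focal pairs and
#'   their planted sign).
#' @export
simulate_correlated_otus <- function(truth = simulation_truth(),
                                     n_samples = truth$otu_n_samples,
                                     seed = truth$seed) {
  sizes <- truth$modules
  if (truth$within_r <= 0 || truth$within_r >= 1) {
    abort("within_r must lie in (0, 1)")
  }
  n_taxa <- sum(sizes)
  module <- rep(seq_along(sizes), sizes)
  ids <- sprintf("OTU_%03d", seq_len(n_taxa))
  focal <- module == truth$focal_module
  n_mixed <- truth$focal_mixed_pos + truth$focal_mixed_neg
  res <- with_seed(seed, {
    # latent factors: shared module factor + idiosyncratic noise
    f <- matrix(rnorm(length(sizes) * n_samples), length(sizes), n_samples)
    eps <- matrix(rnorm(n_taxa * n_samples), n_taxa, n_samples)
    latent <- sqrt(truth$within_r) * f[module, , drop = FALSE] +
      sqrt(1 - truth$within_r) * eps
    mixed_pairs <- NULL
    if (n_mixed > 0) {
      focal_idx <- which(focal)
      other_idx <- which(!focal)
      if (n_mixed > length(other_idx)) {
        abort("not enough non-focal taxa for the requested mixed pairs")
      }
      partners <- sample(other_idx, n_mixed)
      sources <- sample(focal_idx, n_mixed, replace = TRUE)
      signs <- rep(c(1, -1), c(truth$focal_mixed_pos, truth$focal_mixed_neg))
      rho <- truth$mixed_r
      for (m in seq_len(n_mixed)) {
        latent[partners[m], ] <- signs[m] * rho * latent[sources[m], ] +
          sqrt(1 - rho^2) * rnorm(n_samples)
      }
      mixed_pairs <- data.frame(focal = ids[sources],
                                partner = ids[partners],
                                sign = ifelse(signs > 0, "+", "-"))
    }
    list(latent = latent, mixed_pairs = mixed_pairs)
  })
  # mild exponential keeps abundances positive while leaving pairwise
  # Pearson correlations essentially at their planted latent values
  abund <- exp(0.1 * res$latent)
  dimnames(abund) <- list(ids, sprintf("S%03d", seq_len(n_samples)))
  abund <- sweep(abund, 2, colSums(abund), "/")
  tax <- taxonomy_map(data.frame(
    feature_id = ids, domain = "Bacteria",
    phylum = ifelse(focal, truth$focal_phylum,
                    sprintf("Phylum_%d", module))))
  list(abund = rel_abund_table(abund), taxonomy = tax, module = module,
       mixed_pairs = res$mixed_pairs)
}

# Fixed class assignment for the packaged functional genes: substrate
# group determines a plausible CAZy class.
substrate_to_class <- c(cellulose = "GH", hemicellulose = "CE",
                        lignin = "AA", "cello-oligosaccharides" = "GH")

#' Simulate a taxon-annotated CAZyme gene table
#'
#' Per phylum, CAZy-class composition is Dirichlet around a common
#' profile; genes get lognormal lengths within the configured range and
#' negative-binomial counts around RPKM-consistent means. Low-fertility
#' samples multiply the focal phylum's configured CAZy-class means by the
#' planted fold change. The packaged 44 functional genes are embedded
#' (with substrate-group annotations) alongside unannotated CAZy genes.
#'
#' @param truth a [simulation_truth()].
#' @param n_per_class samples per fertility class (default
#'   `truth$n_samples_per_class`).
#' @param fold fertility fold change (default `truth$fertility_fold`; 1
#'   plants no effect).
#' @param seed integer seed (defaults to `truth$seed`).
#' @return A [gene_table()] with fertility metadata in `sample_meta`.
#' @export
simulate_gene_table <- function(truth = simulation_truth(),
                                n_per_class = truth$n_samples_per_class,
                                fold = truth$fertility_fold,
                                seed = truth$seed) {
  if (fold <= 0) abort("fertility fold change must be > 0")
  phyla <- names(truth$phylum_weight)
  catalog <- functional_gene_catalog()
  with_seed(seed, {
    info <- NULL
    mu_rel <- NULL
    for (p in phyla) {
      class_comp <- rgamma(length(CAZY_CLASSES),
                           shape = 50 * truth$cazy_alpha[CAZY_CLASSES])
      class_comp <- class_comp / sum(class_comp)
      names(class_comp) <- CAZY_CLASSES
      fg_class <- substrate_to_class[catalog$substrate_group]
      extra_class <- rep(CAZY_CLASSES, each = truth$genes_per_class)
      all_class <- c(fg_class, extra_class)
      fg <- c(catalog$func_gene, rep(NA_character_, length(extra_class)))
      sg <- c(catalog$substrate_group, rep(NA_character_,
                                           length(extra_class)))
      n_g <- length(all_class)
      # within-class gene weights
      w <- rgamma(n_g, shape = 2)
      rel <- numeric(n_g)
      for (cl in CAZY_CLASSES) {
        idx <- which(all_class == cl)
        rel[idx] <- truth$phylum_weight[[p]] * class_comp[[cl]] *
          w[idx] / sum(w[idx])
      }
      lr <- log(truth$gene_length_range)
      len <- round(pmin(pmax(
        rlnorm(n_g, meanlog = mean(lr), sdlog = diff(lr) / 5),
        truth$gene_length_range[1]), truth$gene_length_range[2]))
      info <- rbind(info, data.frame(
        gene_id = sprintf("%s_g%03d", p, seq_len(n_g)), phylum = p,
        cazy_class = all_class, cazy_family = NA_character_,
        func_gene = fg, substrate_group = sg, length_bp = len,
        stringsAsFactors = FALSE))
      mu_rel <- c(mu_rel, rel)
    }
    mu_rel <- mu_rel / sum(mu_rel)
    n_samples <- 2L * n_per_class
    fertility <- rep(c("high", "low"), each = n_per_class)
    sample_ids <- sprintf("M_%s_%02d", fertility,
                          c(seq_len(n_per_class), seq_len(n_per_class)))
    # expected reads per gene per sample, RPKM-consistent:
    # mu = rel_weight * length_kb (so RPKM ~ rel_weight at equal totals)
    base_mu <- mu_rel * (info$length_bp / 1000)
    base_mu <- base_mu / sum(base_mu) * truth$reads_per_sample
    counts <- matrix(0L, nrow(info), n_samples,
                     dimnames = list(info$gene_id, sample_ids))
    boost <- info$phylum == truth$focal_phylum &
      info$cazy_class %in% truth$fertility_classes
    for (j in seq_len(n_samples)) {
      mu <- base_mu
      if (fertility[j] == "low") mu[boost] <- mu[boost] * fold
      mu <- mu * rlnorm(1, -truth$sample_noise_sdlog^2 / 2,
                        truth$sample_noise_sdlog)
      counts[, j] <- rnbinom(nrow(info), mu = mu,
                             size = 1 / truth$nb_dispersion)
    }
    meta <- data.frame(sample_id = sample_ids, site = "SIP",
                       stage_weeks = rep(rep_len(truth$stages, n_per_class),
                                         2),
                       replicate = seq_len(n_samples),
                       fertility = fertility, stringsAsFactors = FALSE)
    gene_table(info, counts, sample_totals = pmax(colSums(counts), 1),
               sample_meta = meta)
  })
}

#' Generate the full synthetic study bundle
#'
#' Runs every generator under one master seed: chemistry trajectories,
#' the phylum community count table with taxonomy, the block-correlated
#' OTU table for the co-occurrence branch, and the CAZyme gene table.
#'
#' @param truth a [simulation_truth()].
#' @param scale `"full"` (the emulated design: 12 replicates, depth 8000)
#'   or `"ci"` (4x smaller: 3 replicates, depth 2000) for fast runs.
#' @return List of class `study_bundle`: `truth`, `chemistry`, `counts`,
#'   `taxonomy`, `otus` (see [simulate_correlated_otus()]), `genes`.
#' @export
simulate_study <- function(truth = simulation_truth(),
                           scale = c("full", "ci")) {
  scale <- match.arg(scale)
  if (scale == "ci") {
    truth$reps <- max(1L, truth$reps %/% 4L)
    truth$depth <- max(500L, truth$depth %/% 4L)
    truth$n_taxa_per_group <- max(10L, truth$n_taxa_per_group %/% 2L)
  }
  chem <- simulate_chemistry(truth, seed = truth$seed)
  comm <- simulate_communities(chem, truth, seed = truth$seed + 1L)
  otus <- simulate_correlated_otus(truth, seed = truth$seed + 2L)
  genes <- simulate_gene_table(truth, seed = truth$seed + 3L)
  structure(list(truth = truth, chemistry = chem, counts = comm$counts,
                 taxonomy = comm$taxonomy, otus = otus, genes = genes,
                 scale = scale),
            class = "study_bundle")
}

#' Write a study bundle as a TSV + JSON directory
#'
#' Writes `chemistry.tsv`, `counts.tsv`, `sample_meta.tsv`,
#' `taxonomy.tsv`, `otu_abund.tsv`, `otu_taxonomy.tsv`, `genes.tsv`,
#' `gene_meta.tsv` and `truth.json` under `dir`.
#'
#' @param bundle a [simulate_study()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_chemistry(bundle$chemistry, fp("chemistry.tsv"))
  write_count_table(bundle$counts, fp("counts.tsv"), fp("sample_meta.tsv"))
  write_taxonomy(bundle$taxonomy, fp("taxonomy.tsv"))
  ot <- data.frame(feature_id = rownames(bundle$otus$abund$abund),
                   bundle$otus$abund$abund, check.names = FALSE)
  utils::write.table(ot, fp("otu_abund.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_taxonomy(bundle$otus$taxonomy, fp("otu_taxonomy.tsv"))
  write_gene_table(bundle$genes, fp("genes.tsv"))
  utils::write.table(bundle$genes$sample_meta, fp("gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(bundle$truth, fp("truth.json"))
  invisible(dir)
}
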