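# CAZyme and functional-gene attribution metrics from taxon-annotated gene
# tables: RPKM normalization, per-phylum CAZy-class profiles, the
# average-CAZyme ratio, Z-score SD variation across decomposition stages,
# substrate-group roll-ups and soil-fertility contrasts.

GENE_INFO_COLS <- c("gene_id", "phylum", "cazy_class", "cazy_family",
                    "func_gene", "substrate_group", "length_bp")

# matrix slice of a 3-d profile array, dimensions preserved even for a
# single phylum or feature
profile_slab <- function(a, u) {
  matrix(a[, , u], dim(a)[1], dim(a)[2], dimnames = dimnames(a)[1:2])
}

#' Construct a taxon-annotated gene table
#'
#' Holds per-gene annotations (phylum, CAZy class/family, functional-gene
#' id and substrate group — the latter two optional) with per-sample
#' mapped read counts and per-sample totals of mapped reads.
#'
#' @param info data.frame with columns `gene_id`, `phylum`, `cazy_class`
#'   (one of [CAZY_CLASSES] or `NA`), `cazy_family`, `func_gene`,
#'   `substrate_group`, `length_bp` (> 0).
#' @param counts non-negative numeric matrix, genes x samples.
#' @param sample_totals per-sample totals of mapped reads; defaults to the
#'   column sums of `counts` (appropriate when the table is the full
#'   catalog).
#' @param sample_meta optional per-sample metadata (see [count_table()]).
#' @return An object of class `gene_table` with `normalization = "counts"`.
#' @export
gene_table <- function(info, counts, sample_totals = NULL,
                       sample_meta = NULL) {
  info <- as.data.frame(info)
  missing_cols <- setdiff(GENE_INFO_COLS, names(info))
  if (length(missing_cols) > 0) {
    abort("gene info lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  info <- info[, GENE_INFO_COLS]
  info$gene_id <- as.character(info$gene_id)
  if (anyDuplicated(info$gene_id)) abort("duplicated gene ids")
  if (any(is.na(info$length_bp)) || any(info$length_bp <= 0)) {
    abort("gene lengths must be positive")
  }
  bad_class <- !is.na(info$cazy_class) & !info$cazy_class %in% CAZY_CLASSES
  if (any(bad_class)) {
    abort("unknown CAZy class(es): %s",
          paste(unique(info$cazy_class[bad_class]), collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(info)) abort("counts rows must match info rows")
  if (any(counts < 0)) abort("counts must be non-negative")
  rownames(counts) <- info$gene_id
  if (is.null(sample_totals)) sample_totals <- colSums(counts)
  if (length(sample_totals) != ncol(counts)) {
    abort("one mapped-read total per sample required")
  }
  if (any(sample_totals <= 0)) abort("per-sample mapped-read totals must be > 0")
  names(sample_totals) <- colnames(counts)
  structure(list(info = info, counts = counts,
                 sample_totals = sample_totals, sample_meta = sample_meta,
                 abundance = NULL, normalization = "counts"),
            class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("gene_table: %d genes x %d samples (%s)\n", nrow(x$counts),
              ncol(x$counts), x$normalization))
  invisible(x)
}

#' Read / write a taxon-annotated gene table (TSV)
#'
#' Columns: `gene_id`, `phylum`, `cazy_class`, `cazy_family`, `func_gene`,
#' `substrate_group`, `length_bp`, then one count column per sample.
#'
#' @param path source/destination TSV.
#' @param meta_path optional sample-metadata TSV.
#' @name gene_table_io
#' @export
read_gene_table <- function(path, meta_path = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           na.strings = c("NA", ""))
  info <- raw[, GENE_INFO_COLS]
  counts <- as.matrix(raw[, setdiff(names(raw), GENE_INFO_COLS),
                          drop = FALSE])
  meta <- if (!is.null(meta_path)) utils::read.delim(meta_path) else NULL
  gene_table(info, counts, sample_meta = meta)
}

#' @param g a [gene_table()].
#' @rdname gene_table_io
#' @export
write_gene_table <- function(g, path) {
  stopifnot(inherits(g, "gene_table"))
  df <- cbind(g$info, as.data.frame(g$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' RPKM-normalize a gene table
#'
#' Reads assigned per kilobase of target per million mapped reads:
#' `count / (length_bp / 1000) / (total_mapped / 1e6)` for each gene and
#' sample.
#'
#' @param g a [gene_table()].
#' @return The gene table with an `abundance` matrix filled in and
#'   `normalization = "rpkm"`.
#' @export
rpkm_normalize <- function(g) {
  stopifnot(inherits(g, "gene_table"))
  kb <- g$info$length_bp / 1000
  millions <- g$sample_totals / 1e6
  g$abundance <- sweep(g$counts / kb, 2, millions, "/")
  g$normalization <- "rpkm"
  g
}

rpkm_or_die <- function(g) {
  if (is.null(g$abundance)) g <- rpkm_normalize(g)
  g
}

#' Per-phylum CAZy-class attribution profile
#'
#' Sums RPKM per (phylum, CAZy class) and converts to relative shares.
#' With `denominator = "class"` (default) shares are taken within each
#' CAZy class across the listed phyla — "what fraction of the GH pool do
#' Actinobacteria hold"; with `denominator = "table"` against the total
#' over all listed phyla and classes.
#'
#' @param g a [gene_table()] (RPKM-normalized automatically).
#' @param phyla phylum labels to attribute over (the denominators use only
#'   these).
#' @param denominator `"class"` or `"table"`.
#' @param by `"pooled"` (sum across all samples, default), `"stage"`
#'   (per decomposition stage; needs `sample_meta`), or `"sample"`.
#' @return Object of class `cazyme_profile`: `shares` (phylum x class
#'   matrix, or a 3-d array with the stage/sample dimension), `rpkm`
#'   (same shape, unnormalized), `denominator`, `by`, `normalization`.
#' @export
phylum_cazyme_profile <- function(g, phyla,
                                  denominator = c("class", "table"),
                                  by = c("pooled", "stage", "sample")) {
  denominator <- match.arg(denominator)
  by <- match.arg(by)
  g <- rpkm_or_die(g)
  unknown <- setdiff(phyla, unique(g$info$phylum))
  if (length(unknown) > 0) {
    abort("unknown phylum label(s): %s", paste(unknown, collapse = ", "))
  }
  sel <- g$info$phylum %in% phyla & !is.na(g$info$cazy_class)
  for (p in phyla) {
    if (!any(sel & g$info$phylum == p)) {
      abort("phylum '%s' has no CAZy-annotated gene", p)
    }
  }
  ab <- g$abundance[sel, , drop = FALSE]
  ph <- factor(g$info$phylum[sel], levels = phyla)
  cl <- factor(g$info$cazy_class[sel], levels = CAZY_CLASSES)
  units <- switch(by,
    pooled = factor(rep("pooled", ncol(ab))),
    sample = factor(colnames(ab), levels = colnames(ab)),
    stage = {
      if (is.null(g$sample_meta)) abort("by='stage' needs sample metadata")
      factor(g$sample_meta$stage_weeks[match(colnames(ab),
                                             g$sample_meta$sample_id)])
    })
  rpkm <- array(0, dim = c(length(phyla), length(CAZY_CLASSES),
                           nlevels(units)),
                dimnames = list(phyla, CAZY_CLASSES, levels(units)))
  for (u in seq_len(nlevels(units))) {
    cols <- which(as.integer(units) == u)
    sums <- tapply(rowSums(ab[, cols, drop = FALSE]),
                   list(ph, cl), sum, default = 0)
    rpkm[, , u] <- sums
  }
  shares <- rpkm
  for (u in seq_len(dim(rpkm)[3])) {
    slab <- profile_slab(rpkm, u)
    denom <- if (denominator == "class") {
      rep(colSums(slab), each = length(phyla))
    } else {
      sum(slab)
    }
    s <- slab / denom
    s[!is.finite(s)] <- 0  # empty class across all phyla
    shares[, , u] <- s
  }
  if (by == "pooled") {
    shares <- profile_slab(shares, 1)
    rpkm <- profile_slab(rpkm, 1)
  }
  structure(list(shares = shares, rpkm = rpkm, denominator = denominator,
                 by = by, features = CAZY_CLASSES, phyla = phyla,
                 normalization = "rpkm"),
            class = "cazyme_profile")
}

#' @export
print.cazyme_profile <- function(x, ...) {
  cat(sprintf("cazyme_profile: %d phyla x %d features (%s denominator, by %s)\n",
              length(x$phyla), length(x$features), x$denominator, x$by))
  invisible(x)
}

#' Average-CAZyme ratio per phylum
#'
#' Ratio of a phylum's share of CAZyme abundance to its share of
#' whole-community taxonomic abundance. A ratio above 1 marks a phylum
#' encoding disproportionately many CAZymes for its population size (the
#' situation of Actinobacteria: a small population holding a large CAZyme
#' repertoire). Scale-free: multiplying all RPKM by a constant leaves it
#' unchanged.
#'
#' @param caz_share named numeric, CAZyme relative abundance per phylum.
#' @param taxa_share named numeric, taxonomic relative abundance per
#'   phylum (all strictly positive).
#' @return Named numeric vector of ratios, one per phylum of `caz_share`.
#' @export
average_cazyme_ratio <- function(caz_share, taxa_share) {
  if (is.null(names(caz_share)) || is.null(names(taxa_share))) {
    abort("both share vectors must be named by phylum")
  }
  absent <- setdiff(names(caz_share), names(taxa_share))
  if (length(absent) > 0) {
    abort("no taxonomic share for phylum: %s", paste(absent, collapse = ", "))
  }
  ts <- taxa_share[names(caz_share)]
  zero <- ts <= 0
  if (any(zero)) {
    abort("zero taxonomic share for phylum: %s",
          paste(names(caz_share)[zero], collapse = ", "))
  }
  caz_share / ts
}

#' Z-score SD variation of attribution profiles across stages
#'
#' Quantifies how variable each phylum's feature shares are over
#' decomposition stages. Per feature (CAZy class or substrate group), the
#' phylum x stage panel of shares is Z-score transformed (mean 0, SD 1
#' over the pooled panel by default), and each phylum's variation is the
#' standard deviation of its own Z-scored stage series. Averaging across
#' features gives the per-phylum mean variation; stable groups such as
#' Actinobacteria/Acidobacteria show small values.
#'
#' @param p a [phylum_cazyme_profile()] (or [substrate_group_rollup()])
#'   computed with `by = "stage"` and at least 3 stages.
#' @param scope Z-scoring scope: `"pooled"` (over the whole phylum x
#'   stage panel per feature, default) or `"per_phylum"` (each phylum's
#'   stage series scaled by its own mean/SD).
#' @return Object of class `variation_profile`: `sd` (phylum x feature
#'   matrix), `mean_variation` (per-phylum mean over features), `scope`.
#' @export
variation_profile <- function(p, scope = c("pooled", "per_phylum")) {
  scope <- match.arg(scope)
  stopifnot(inherits(p, "cazyme_profile"))
  if (p$by != "stage" || length(dim(p$shares)) != 3) {
    abort("variation_profile needs a profile computed with by = 'stage'")
  }
  n_stage <- dim(p$shares)[3]
  if (n_stage < 3) abort("need at least 3 stages")
  phyla <- p$phyla
  features <- p$features
  sds <- matrix(0, length(phyla), length(features),
                dimnames = list(phyla, features))
  for (f in seq_along(features)) {
    panel <- p$shares[, f, ]  # phylum x stage
    if (scope == "pooled") {
      s <- sd(as.vector(panel))
      if (s == 0) {
        warning(sprintf("feature '%s': constant panel, variation set to 0",
                        features[f]))
        next
      }
      z <- (panel - mean(panel)) / s
      sds[, f] <- apply(z, 1, sd)
    } else {
      for (i in seq_along(phyla)) {
        s <- sd(panel[i, ])
        sds[i, f] <- if (s == 0) 0 else sd((panel[i, ] - mean(panel[i, ])) / s)
      }
    }
  }
  structure(list(sd = sds, mean_variation = rowMeans(sds), scope = scope),
            class = "variation_profile")
}

#' @export
print.variation_profile <- function(x, ...) {
  cat("variation_profile (mean Z-score SD per phylum):\n")
  mv <- sort(x$mean_variation)
  for (p in names(mv)) cat(sprintf("  %-20s %.3f\n", p, mv[p]))
  invisible(x)
}

#' The packaged functional-gene catalog
#'
#' Returns the packaged mapping of 44 plant-residue-decomposition
#' functional genes to their four substrate groups (cellulose,
#' hemicellulose, lignin, cello-oligosaccharides degradation). The catalog
#' is a curated synthetic stand-in — gene ids are treated as opaque
#' strings throughout the package, so users can substitute their own
#' catalog TSV (columns `func_gene`, `substrate_group`).
#'
#' @param path optional path to a replacement catalog TSV.
#' @return data.frame with columns `func_gene`, `substrate_group`.
#' @export
functional_gene_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_genes_synthetic.tsv",
                        package = "strawdecomp", mustWork = TRUE)
  }
  map <- utils::read.delim(path)
  if (!all(c("func_gene", "substrate_group") %in% names(map))) {
    abort("catalog needs columns func_gene and substrate_group")
  }
  map
}

#' Roll functional genes up into substrate groups
#'
#' Sums RPKM within each of the four substrate-degradation groups per
#' phylum (and per sample/stage), conserving total mass. Every functional
#' gene present in the table must be covered by the mapping; groups with
#' no gene are kept as zero rows.
#'
#' @param g a [gene_table()] whose functional genes are annotated in
#'   `info$func_gene`.
#' @param mapping data.frame `func_gene` -> `substrate_group`; defaults to
#'   [functional_gene_catalog()].
#' @param phyla phylum labels to keep (default: all phyla with a
#'   functional gene).
#' @param by aggregation unit as in [phylum_cazyme_profile()].
#' @param denominator share denominator as in [phylum_cazyme_profile()].
#' @return A `cazyme_profile` whose features are [SUBSTRATE_GROUPS].
#' @export
substrate_group_rollup <- function(g, mapping = functional_gene_catalog(),
                                   phyla = NULL,
                                   by = c("pooled", "stage", "sample"),
                                   denominator = c("class", "table")) {
  by <- match.arg(by)
  denominator <- match.arg(denominator)
  g <- rpkm_or_die(g)
  sel <- !is.na(g$info$func_gene)
  if (!any(sel)) abort("gene table has no functional-gene annotations")
  genes <- g$info$func_gene[sel]
  unmapped <- setdiff(unique(genes), mapping$func_gene)
  if (length(unmapped) > 0) {
    abort("functional gene(s) missing from mapping: %s",
          paste(unmapped, collapse = ", "))
  }
  group <- mapping$substrate_group[match(genes, mapping$func_gene)]
  bad <- setdiff(unique(group), SUBSTRATE_GROUPS)
  if (length(bad) > 0) {
    abort("unknown substrate group(s): %s", paste(bad, collapse = ", "))
  }
  if (is.null(phyla)) phyla <- sort(unique(g$info$phylum[sel]))
  keep <- sel & g$info$phylum %in% phyla
  ab <- g$abundance[keep, , drop = FALSE]
  ph <- factor(g$info$phylum[keep], levels = phyla)
  grp <- factor(mapping$substrate_group[match(g$info$func_gene[keep],
                                              mapping$func_gene)],
                levels = SUBSTRATE_GROUPS)
  units <- switch(by,
    pooled = factor(rep("pooled", ncol(ab))),
    sample = factor(colnames(ab), levels = colnames(ab)),
    stage = {
      if (is.null(g$sample_meta)) abort("by='stage' needs sample metadata")
      factor(g$sample_meta$stage_weeks[match(colnames(ab),
                                             g$sample_meta$sample_id)])
    })
  rpkm <- array(0, dim = c(length(phyla), length(SUBSTRATE_GROUPS),
                           nlevels(units)),
                dimnames = list(phyla, SUBSTRATE_GROUPS, levels(units)))
  for (u in seq_len(nlevels(units))) {
    cols <- which(as.integer(units) == u)
    rpkm[, , u] <- tapply(rowSums(ab[, cols, drop = FALSE]),
                          list(ph, grp), sum, default = 0)
  }
  shares <- rpkm
  for (u in seq_len(dim(rpkm)[3])) {
    slab <- profile_slab(rpkm, u)
    denom <- if (denominator == "class") {
      rep(colSums(slab), each = length(phyla))
    } else {
      sum(slab)
    }
    s <- slab / denom
    s[!is.finite(s)] <- 0
    shares[, , u] <- s
  }
  if (by == "pooled") {
    shares <- profile_slab(shares, 1)
    rpkm <- profile_slab(rpkm, 1)
  }
  structure(list(shares = shares, rpkm = rpkm, denominator = denominator,
                 by = by, features = SUBSTRATE_GROUPS, phyla = phyla,
                 normalization = "rpkm"),
            class = "cazyme_profile")
}

#' Soil-fertility contrast of feature abundances
#'
#' Compares per-feature relative abundances between high- and low-
#' fertility samples with a Welch two-sample t test on (by default)
#' log-transformed shares, the comparison behind boxplot panels of phylum
#' and gene-class abundances under contrasting soil fertilities. Zeros are
#' shifted by half the smallest nonzero value before the natural log.
#'
#' @param x numeric feature x sample matrix of relative abundances.
#' @param fertility `"high"`/`"low"` label per sample column (each class
#'   needs at least 3 samples).
#' @param log_transform apply the log transform (default `TRUE`).
#' @return data.frame, one row per feature: `feature`, `mean_high`,
#'   `mean_low` (on the transformed scale used for testing), `p_value`,
#'   `signif` (`"**"` p < 0.01, `"*"` p < 0.05, `"n.s."` otherwise).
#' @export
fertility_contrast <- function(x, fertility, log_transform = TRUE) {
  x <- as.matrix(x)
  fertility <- as.character(fertility)
  if (length(fertility) != ncol(x)) abort("one fertility label per sample")
  for (cls in c("high", "low")) {
    if (sum(fertility == cls, na.rm = TRUE) < 3) {
      abort("fertility class '%s' needs at least 3 samples", cls)
    }
  }
  if (log_transform) {
    pos <- x[x > 0]
    pc <- if (length(pos) == 0) 1e-12 else min(pos) / 2
    x <- log(x + pc)
  }
  hi <- which(fertility == "high")
  lo <- which(fertility == "low")
  res <- lapply(seq_len(nrow(x)), function(i) {
    a <- x[i, hi]
    b <- x[i, lo]
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      t.test(a, b)$p.value
    }
    data.frame(feature = rownames(x)[i] %||% as.character(i),
               mean_high = mean(a), mean_low = mean(b), p_value = p)
  })
  out <- do.call(rbind, res)
  out$signif <- ifelse(out$p_value < 0.01, "**",
                       ifelse(out$p_value < 0.05, "*", "n.s."))
  rownames(out) <- NULL
  out
}
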