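#' Taxonomic ranks used throughout the package
#'
#' The seven-rank lineage, domain to species, in order.
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Straw chemistry components
#'
#' The four measured straw components: cellulose, hemicellulose, lignin and
#' water-soluble polysaccharides (WSP), each a mass fraction of dry straw.
#' @export
CHEMISTRY_COMPONENTS <- c("cellulose", "hemicellulose", "lignin", "wsp")

#' The six CAZy enzyme classes
#'
#' Glycoside hydrolases (GH), glycosyl transferases (GT), polysaccharide
#' lyases (PL), carbohydrate esterases (CE), carbohydrate-binding modules
#' (CBM) and auxiliary activities (AA).
#' @export
CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "CBM", "AA")

#' The four substrate groups for functional-gene roll-ups
#' @export
SUBSTRATE_GROUPS <- c("cellulose", "hemicellulose", "lignin",
                      "cello-oligosaccharides")

# ---------------------------------------------------------------------------
# CountTable
# ---------------------------------------------------------------------------

#' Construct a taxon-by-sample count table
#'
#' A `count_table` holds non-negative integer counts (taxa in rows, samples
#' in columns) together with per-sample metadata: site, decomposition stage
#' in weeks, replicate and soil-fertility class.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples,
#'   with row and column names.
#' @param sample_meta data.frame with columns `sample_id`, `site`,
#'   `stage_weeks`, `replicate`, `fertility` (values `"high"`, `"low"` or
#'   `NA`), one row per sample column of `counts`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have taxon row names and sample column names")
  }
  if (anyDuplicated(colnames(counts))) abort("sample ids must be unique")
  if (anyDuplicated(rownames(counts))) abort("taxon ids must be unique")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort("non-integer or negative count at taxon '%s', sample '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  sample_meta <- validate_sample_meta(sample_meta, colnames(counts))
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_table")
}

validate_sample_meta <- function(meta, sample_ids) {
  need <- c("sample_id", "site", "stage_weeks", "replicate", "fertility")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort("sample metadata lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  meta <- as.data.frame(meta)[, need]
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("duplicated sample ids in metadata")
  absent <- setdiff(sample_ids, meta$sample_id)
  if (length(absent) > 0) {
    abort("sample(s) missing metadata: %s", paste(absent, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  meta$stage_weeks <- as.numeric(meta$stage_weeks)
  if (any(is.na(meta$stage_weeks)) || any(meta$stage_weeks <= 0)) {
    abort("stage_weeks must be positive for every sample")
  }
  ok_fert <- meta$fertility %in% c("high", "low") | is.na(meta$fertility)
  if (!all(ok_fert)) abort("fertility must be 'high', 'low' or NA")
  core <- meta[, c("site", "stage_weeks", "replicate")]
  if (anyNA(core)) abort("site, stage_weeks and replicate must be complete")
  meta
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Read a count table and its sample metadata from TSV
#'
#' The count file is tab-delimited with a header row of sample ids and a
#' first column `feature_id`; the metadata file has columns `sample_id`,
#' `site`, `stage_weeks`, `replicate`, `fertility`.
#'
#' @param path path to the count TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, meta_path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "feature_id") {
    abort("first column of %s must be 'feature_id'", path)
  }
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort("non-integer or negative count at taxon '%s', sample '%s' in %s",
          ids[bad[1, 1]], colnames(mat)[bad[1, 2]], path)
  }
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  count_table(num, meta)
}

#' Write a count table (and optionally its metadata) to TSV
#'
#' @param t a [count_table()].
#' @param path destination TSV for the counts.
#' @param meta_path optional destination TSV for the sample metadata.
#' @export
write_count_table <- function(t, path, meta_path = NULL) {
  stopifnot(inherits(t, "count_table"))
  df <- data.frame(feature_id = rownames(t$counts), t$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(t$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# TaxonomyMap
# ---------------------------------------------------------------------------

#' Construct a taxonomy map
#'
#' Maps taxon ids to a seven-rank lineage (domain..species). Ranks may be
#' unassigned (`NA`) from any point downward, but a lineage may not have a
#' gap (an assigned rank below an unassigned one).
#'
#' @param df data.frame with column `feature_id` and the columns of
#'   [TAXONOMY_RANKS] (missing trailing ranks are added as `NA`).
#' @return An object of class `taxonomy_map` (a validated data.frame).
#' @export
taxonomy_map <- function(df) {
  df <- as.data.frame(df)
  if (!"feature_id" %in% names(df)) abort("taxonomy needs a feature_id column")
  for (r in TAXONOMY_RANKS) if (!r %in% names(df)) df[[r]] <- NA_character_
  df <- df[, c("feature_id", TAXONOMY_RANKS)]
  df$feature_id <- as.character(df$feature_id)
  for (r in TAXONOMY_RANKS) {
    v <- as.character(df[[r]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[r]] <- v
  }
  if (anyDuplicated(df$feature_id)) abort("duplicated feature_id in taxonomy")
  ranks <- as.matrix(df[, TAXONOMY_RANKS])
  assigned <- !is.na(ranks)
  # no rank gaps: once unassigned, all deeper ranks unassigned
  gap <- apply(assigned, 1, function(a) any(diff(a) > 0))
  if (any(gap)) {
    abort("lineage gap (assigned rank below an unassigned one) for taxon '%s'",
          df$feature_id[which(gap)[1]])
  }
  rownames(df) <- df$feature_id
  structure(df, class = c("taxonomy_map", "data.frame"))
}

#' Read a taxonomy map from TSV
#'
#' @param path TSV with columns `feature_id`, `domain` .. `species`.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_map(utils::read.delim(path, check.names = FALSE,
                                 colClasses = "character",
                                 na.strings = c("NA", "")))
}

#' Write a taxonomy map to TSV
#' @param tax a [taxonomy_map()].
#' @param path destination file.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

check_taxa_covered <- function(taxa, tax) {
  absent <- setdiff(taxa, tax$feature_id)
  if (length(absent) > 0) {
    abort("taxa missing from taxonomy map: %s",
          paste(utils::head(absent, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# ChemistryTable
# ---------------------------------------------------------------------------

#' Construct a straw chemistry table
#'
#' Per-sample mass fractions of the four straw components (cellulose,
#' hemicellulose, lignin, WSP), each in \[0, 1\], with no missing values.
#'
#' @param df data.frame with columns `sample_id` and [CHEMISTRY_COMPONENTS].
#' @return An object of class `chemistry_table`.
#' @export
chemistry_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", CHEMISTRY_COMPONENTS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort("chemistry table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicated sample ids in chemistry")
  comp <- as.matrix(df[, CHEMISTRY_COMPONENTS])
  if (anyNA(comp)) abort("chemistry table has missing component values")
  if (any(comp < 0 | comp > 1)) {
    abort("chemistry components must be mass fractions in [0, 1]")
  }
  rownames(df) <- df$sample_id
  structure(df, class = c("chemistry_table", "data.frame"))
}

#' Read a straw chemistry table from TSV
#' @param path TSV with columns `sample_id`, `cellulose`, `hemicellulose`,
#'   `lignin`, `wsp`.
#' @return A [chemistry_table()].
#' @export
read_chemistry <- function(path) {
  chemistry_table(utils::read.delim(path, check.names = FALSE))
}

#' Write a chemistry table to TSV
#' @param c a [chemistry_table()].
#' @param path destination file.
#' @export
write_chemistry <- function(c, path) {
  utils::write.table(as.data.frame(c), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Preprocessing
# ---------------------------------------------------------------------------

#' Rarefy a count table to a fixed depth
#'
#' Subsamples every sample column to exactly `depth` reads without
#' replacement (multivariate hypergeometric draw), the standard
#' normalization before community dissimilarity analyses. The field study
#' this package emulates rarefied all samples to 8000 reads.
#'
#' @param t a [count_table()].
#' @param depth positive integer target depth; every sample must have at
#'   least this many reads.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return A rarefied [count_table()] with every column summing to `depth`.
#' @export
rarefy <- function(t, depth, seed) {
  stopifnot(inherits(t, "count_table"), depth > 0)
  depth <- as.integer(depth)
  totals <- colSums(t$counts)
  low <- totals < depth
  if (any(low)) {
    abort("sample(s) below depth %d: %s", depth,
          paste(colnames(t$counts)[low], collapse = ", "))
  }
  out <- with_seed(seed, {
    cols <- vapply(seq_len(ncol(t$counts)), function(j) {
      col <- t$counts[, j]
      if (totals[j] == depth) return(col)
      taxon_of <- rep.int(seq_along(col), col)
      drawn <- sample(taxon_of, depth, replace = FALSE)
      tabulate(drawn, nbins = length(col))
    }, integer(nrow(t$counts)))
    matrix(cols, nrow = nrow(t$counts), ncol = ncol(t$counts),
           dimnames = dimnames(t$counts))
  })
  res <- count_table(out, t$sample_meta)
  attr(res, "rarefied_depth") <- depth
  res
}

#' Convert counts to relative abundances
#'
#' Closes each sample column to sum 1. The result carries a provenance flag
#' recording whether the input counts were rarefied.
#'
#' @param t a [count_table()].
#' @return A `rel_abund_table`: list with `abund` (taxa x samples, columns
#'   sum to 1), `provenance` (`"raw"` or `"rarefied"`) and `sample_meta`.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "count_table"))
  totals <- colSums(t$counts)
  if (any(totals == 0)) {
    abort("all-zero sample(s): %s",
          paste(colnames(t$counts)[totals == 0], collapse = ", "))
  }
  abund <- sweep(t$counts, 2, totals, "/")
  rel_abund_table(abund,
                  provenance = if (is.null(attr(t, "rarefied_depth")))
                    "raw" else "rarefied",
                  sample_meta = t$sample_meta)
}

#' Construct a relative-abundance table
#'
#' @param abund numeric matrix, taxa x samples, entries in \[0, 1\]. Columns
#'   must sum to 1 unless `subset_fraction` records a per-sample subset mass.
#' @param provenance `"raw"` or `"rarefied"`.
#' @param sample_meta optional per-sample metadata data.frame.
#' @param subset_fraction optional named numeric: the fraction of whole-
#'   community mass each column retains after a lineage subset.
#' @return An object of class `rel_abund_table`.
#' @export
rel_abund_table <- function(abund, provenance = "raw", sample_meta = NULL,
                            subset_fraction = NULL) {
  abund <- as.matrix(abund)
  if (any(abund < -1e-12) || any(abund > 1 + 1e-9)) {
    abort("relative abundances must lie in [0, 1]")
  }
  sums <- colSums(abund)
  if (is.null(subset_fraction)) {
    if (any(abs(sums - 1) > 1e-9)) {
      abort("sample columns must sum to 1 (max deviation %.3g)",
            max(abs(sums - 1)))
    }
  } else if (any(sums > 1 + 1e-9)) {
    abort("subset columns may not exceed whole-community mass 1")
  }
  structure(list(abund = abund, provenance = provenance,
                 sample_meta = sample_meta,
                 subset_fraction = subset_fraction),
            class = "rel_abund_table")
}

#' @export
print.rel_abund_table <- function(x, ...) {
  cat(sprintf("rel_abund_table: %d taxa x %d samples (%s%s)\n",
              nrow(x$abund), ncol(x$abund), x$provenance,
              if (is.null(x$subset_fraction)) "" else ", lineage subset"))
  invisible(x)
}

#' Subset a relative-abundance table to one lineage
#'
#' Restricts rows to taxa under a rank path (e.g. phylum = Actinobacteria)
#' and records, per sample, the fraction of whole-community mass the subset
#' retains. With `renormalize = TRUE` columns are re-closed to 1 so that
#' within-group composition can be compared across samples; the
#' unrenormalized fractions remain available for attribution ratios.
#'
#' @param t a [rel_abund_table()] over the whole community.
#' @param tax a [taxonomy_map()] covering all taxa of `t`.
#' @param lineage named character vector of rank = label pairs, e.g.
#'   `c(phylum = "Actinobacteria")`.
#' @param renormalize logical; re-close subset columns to sum 1.
#' @return A [rel_abund_table()] with `subset_fraction` set (dropped when
#'   `renormalize = TRUE`, where the fractions move to attribute
#'   `"parent_fraction"`).
#' @export
subset_by_lineage <- function(t, tax, lineage, renormalize = FALSE) {
  stopifnot(inherits(t, "rel_abund_table"), inherits(tax, "taxonomy_map"))
  if (is.null(names(lineage)) || !all(names(lineage) %in% TAXONOMY_RANKS)) {
    abort("lineage must be a named vector over ranks %s",
          paste(TAXONOMY_RANKS, collapse = ", "))
  }
  check_taxa_covered(rownames(t$abund), tax)
  lin <- tax[match(rownames(t$abund), tax$feature_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(t$abund))
  for (r in names(lineage)) {
    keep <- keep & !is.na(lin[[r]]) & lin[[r]] == lineage[[r]]
  }
  if (!any(keep)) {
    abort("lineage prefix (%s) matches no taxa",
          paste(names(lineage), lineage, sep = "=", collapse = ", "))
  }
  sub <- t$abund[keep, , drop = FALSE]
  frac <- colSums(sub)
  if (renormalize) {
    if (any(frac == 0)) {
      abort("cannot renormalize: subset has zero mass in sample(s) %s",
            paste(colnames(sub)[frac == 0], collapse = ", "))
    }
    out <- rel_abund_table(sweep(sub, 2, frac, "/"),
                           provenance = t$provenance,
                           sample_meta = t$sample_meta)
    attr(out, "parent_fraction") <- frac
    out
  } else {
    rel_abund_table(sub, provenance = t$provenance,
                    sample_meta = t$sample_meta, subset_fraction = frac)
  }
}

#' Aggregate a relative-abundance table at a taxonomic rank
#'
#' Pools rows by their label at `rank`; taxa unassigned at that rank are
#' pooled as `"unclassified:<deepest assigned parent>"` so per-sample mass
#' is conserved exactly.
#'
#' @param t a [rel_abund_table()].
#' @param tax a [taxonomy_map()] covering all taxa of `t`.
#' @param rank one of [TAXONOMY_RANKS].
#' @return A [rel_abund_table()] whose rows are rank labels.
#' @export
aggregate_by_rank <- function(t, tax, rank) {
  stopifnot(inherits(t, "rel_abund_table"), inherits(tax, "taxonomy_map"))
  if (!rank %in% TAXONOMY_RANKS) abort("unknown rank '%s'", rank)
  check_taxa_covered(rownames(t$abund), tax)
  lin <- tax[match(rownames(t$abund), tax$feature_id), , drop = FALSE]
  labels <- as.character(lin[[rank]])
  if (anyNA(labels)) {
    na_idx <- which(is.na(labels))
    parent <- vapply(na_idx, function(i) {
      assigned <- unlist(lin[i, TAXONOMY_RANKS])
      assigned <- assigned[!is.na(assigned)]
      if (length(assigned) == 0) "root" else assigned[length(assigned)]
    }, character(1))
    labels[na_idx] <- paste0("unclassified:", parent)
  }
  agg <- rowsum(t$abund, group = labels, reorder = TRUE)
  rel_abund_table(agg, provenance = t$provenance, sample_meta = t$sample_meta,
                  subset_fraction = t$subset_fraction)
}
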