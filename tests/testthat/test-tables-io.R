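# Count-table IO, rarefaction and relative-abundance preprocessing.

test_that("count tables read back what was written and validate cells", {
  t <- fixture_count_table()
  dir <- withr::local_tempdir()
  write_count_table(t, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  back <- read_count_table(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  expect_identical(back$counts, t$counts)
  expect_identical(back$sample_meta, t$sample_meta)

  small <- data.frame(feature_id = c("t1", "t2"), s1 = c(3, 1), s2 = c(0, 2))
  write.table(small, file.path(dir, "small.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = c("s1", "s2"), site = "CS",
                     stage_weeks = 1, replicate = 1:2, fertility = "high")
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct <- read_count_table(file.path(dir, "small.tsv"),
                         file.path(dir, "meta.tsv"))
  expect_equal(unname(colSums(ct$counts)), c(4, 2))

  bad <- small
  bad$s1[2] <- -1
  write.table(bad, file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_count_table(file.path(dir, "bad.tsv"),
                                file.path(dir, "meta.tsv")),
               "t2.*s1")
})

test_that("metadata is required, complete and matched to samples", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample_id = "s1", site = "CS", stage_weeks = 1,
                     replicate = 1, fertility = NA)
  expect_error(count_table(m, meta), "missing metadata: s2")
  meta2 <- data.frame(sample_id = c("s1", "s2"), site = "CS",
                      stage_weeks = c(1, -2), replicate = 1:2,
                      fertility = NA)
  expect_error(count_table(m, meta2), "stage_weeks")
})

test_that("rarefaction hits the target depth and is reproducible", {
  t <- fixture_count_table(n_taxa = 10, n_samples = 5, lambda = 200)
  r <- rarefy(t, 500, seed = 3)
  expect_true(all(colSums(r$counts) == 500))
  expect_identical(r$counts, rarefy(t, 500, seed = 3)$counts)
  # idempotent at the table's own depth
  expect_identical(rarefy(r, 500, seed = 9)$counts, r$counts)

  one <- count_table(matrix(10, 1, 1, dimnames = list("t1", "s1")),
                     data.frame(sample_id = "s1", site = "CS",
                                stage_weeks = 1, replicate = 1,
                                fertility = NA))
  expect_equal(unname(rarefy(one, 5, seed = 1)$counts[1, 1]), 5L)
  expect_error(rarefy(one, 11, seed = 1), "below depth")
})

test_that("rarefaction is a without-replacement hypergeometric draw", {
  # two taxa 9000/1000, depth 8000: mean subsample of taxon 1 is
  # 8000 * 0.9 = 7200 with hypergeometric variance
  t <- count_table(matrix(c(9000L, 1000L), 2, 1,
                          dimnames = list(c("a", "b"), "s1")),
                   data.frame(sample_id = "s1", site = "CS",
                              stage_weeks = 1, replicate = 1,
                              fertility = NA))
  draws <- vapply(seq_len(2000), function(s) {
    rarefy(t, 8000, seed = s)$counts[1, 1]
  }, integer(1))
  # hypergeometric: var = n * p * (1-p) * (N-n)/(N-1)
  v <- 8000 * 0.9 * 0.1 * (10000 - 8000) / (10000 - 1)
  se <- sqrt(v / 2000)
  expect_lt(abs(mean(draws) - 7200), 3 * se)
  expect_true(all(draws <= 8000) && all(draws >= 7000))
})

test_that("relative abundances close each sample to exactly one", {
  t <- fixture_count_table(n_taxa = 12, n_samples = 6, seed = 5)
  rel <- to_relative_abundance(t)
  expect_true(all(abs(colSums(rel$abund) - 1) < 1e-12))
  expect_equal(rel$provenance, "raw")
  expect_equal(to_relative_abundance(rarefy(t, 100, seed = 1))$provenance,
               "rarefied")

  m <- matrix(c(2, 2, 8000, 0), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), site = "CS",
                     stage_weeks = 1, replicate = 1:2, fertility = NA)
  rel2 <- to_relative_abundance(count_table(m, meta))
  expect_equal(unname(rel2$abund[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(rel2$abund[, "s2"]), c(1, 0))

  m[, 2] <- 0
  expect_error(to_relative_abundance(count_table(m, meta)), "all-zero")
})

test_that("lineage subsetting records fractions and renormalizes", {
  abund <- matrix(c(0.02, 0.016, 0.01, 0.954,
                    0.03, 0.01, 0.006, 0.954), 4,
                  dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  rel <- rel_abund_table(abund)
  tax <- fixture_taxonomy(paste0("t", 1:4),
                          c("Actinobacteria", "Actinobacteria",
                            "Actinobacteria", "Proteobacteria"))
  sub <- subset_by_lineage(rel, tax, c(phylum = "Actinobacteria"))
  expect_equal(unname(sub$subset_fraction["s1"]), 0.046)
  ren <- subset_by_lineage(rel, tax, c(phylum = "Actinobacteria"),
                           renormalize = TRUE)
  expect_true(all(abs(colSums(ren$abund) - 1) < 1e-12))
  expect_equal(unname(attr(ren, "parent_fraction")["s1"]), 0.046)

  # a prefix covering everything is the identity with fraction 1
  all_tax <- fixture_taxonomy(paste0("t", 1:4), rep("Proteobacteria", 4))
  idsub <- subset_by_lineage(rel, all_tax, c(phylum = "Proteobacteria"))
  expect_equal(idsub$abund, rel$abund)
  expect_true(all(abs(idsub$subset_fraction - 1) < 1e-12))

  expect_error(subset_by_lineage(rel, tax, c(phylum = "Firmicutes")),
               "matches no taxa")

  # fractions over a partition of phyla sum to one per sample
  fr <- subset_by_lineage(rel, tax, c(phylum = "Actinobacteria"))$subset_fraction +
    subset_by_lineage(rel, tax, c(phylum = "Proteobacteria"))$subset_fraction
  expect_true(all(abs(fr - 1) < 1e-12))
})

test_that("rank aggregation pools unassigned taxa and conserves mass", {
  t <- fixture_count_table(n_taxa = 8, n_samples = 5, seed = 21)
  rel <- to_relative_abundance(t)
  fams <- c("F1", "F1", "F2", NA, NA, "F2", "F3", "F1")
  tax <- fixture_taxonomy(rownames(rel$abund), "Actinobacteria",
                          family = fams)
  agg <- aggregate_by_rank(rel, tax, "family")
  expect_true(all(abs(colSums(agg$abund) - colSums(rel$abund)) < 1e-12))
  expect_true("unclassified:Actinobacteria" %in% rownames(agg$abund))
  expect_equal(unname(agg$abund["F1", ]),
               unname(colSums(rel$abund[fams %in% "F1", ])))

  # aggregating at the identity rank permutes the rows
  tax2 <- fixture_taxonomy(rownames(rel$abund),
                           paste0("P", seq_len(nrow(rel$abund))))
  agg2 <- aggregate_by_rank(rel, tax2, "phylum")
  expect_equal(unname(sort(rowSums(agg2$abund))),
               unname(sort(rowSums(rel$abund))))
  expect_error(aggregate_by_rank(rel, tax, "subclade"), "unknown rank")
})

test_that("taxonomy lineages reject rank gaps", {
  expect_error(taxonomy_map(data.frame(feature_id = "x", domain = "Bacteria",
                                       phylum = NA, class = "Gap")),
               "lineage gap")
})
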