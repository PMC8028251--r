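# RPKM normalization, CAZyme attribution profiles, variation and
# fertility contrasts.

make_gene_fixture <- function() {
  info <- data.frame(
    gene_id = paste0("g", 1:6),
    phylum = c("Actinobacteria", "Actinobacteria", "Proteobacteria",
               "Proteobacteria", "Actinobacteria", "Proteobacteria"),
    cazy_class = c("GH", "GT", "GH", "GT", "CE", "CE"),
    cazy_family = NA, func_gene = NA, substrate_group = NA,
    length_bp = c(1000, 2000, 500, 1000, 1500, 1500))
  counts <- matrix(c(100, 40, 50, 20, 30, 30,
                     200, 80, 100, 40, 60, 60), 6, 2,
                   dimnames = list(info$gene_id, c("s1", "s2")))
  gene_table(info, counts, sample_totals = c(s1 = 1e6, s2 = 2e6))
}

test_that("RPKM normalization follows its defining scaling laws", {
  g <- make_gene_fixture()
  r <- rpkm_normalize(g)
  # unit case: 100 reads, 1 kb gene, 1e6 mapped reads -> 100
  expect_equal(r$abundance["g1", "s1"], 100)
  # doubling the library total halves RPKM
  expect_equal(r$abundance["g1", "s2"], 100)  # counts also doubled
  expect_equal(r$abundance[, "s2"] / r$abundance[, "s1"],
               setNames(rep(1, 6), rownames(r$abundance)))
  # full oracle
  for (j in 1:2) {
    expect_equal(r$abundance[, j],
                 oracle_rpkm(g$counts[, j], g$info$length_bp,
                             g$sample_totals[j]),
                 tolerance = 1e-10)
  }
  # doubling length halves RPKM
  g2 <- g
  g2$info$length_bp <- 2 * g$info$length_bp
  expect_equal(rpkm_normalize(g2)$abundance, r$abundance / 2,
               tolerance = 1e-12)
})

test_that("phylum profiles attribute CAZy classes with chosen denominators", {
  g <- make_gene_fixture()
  prof <- phylum_cazyme_profile(g, c("Actinobacteria", "Proteobacteria"),
                                denominator = "class")
  # shares sum to one within each non-empty class
  nz <- colSums(prof$rpkm) > 0
  expect_true(all(abs(colSums(prof$shares)[nz] - 1) < 1e-12))
  # single listed phylum holds share one in its non-empty classes
  solo <- phylum_cazyme_profile(g, "Actinobacteria", denominator = "class")
  expect_true(all(solo$shares[1, colSums(solo$rpkm) > 0] == 1))
  expect_error(phylum_cazyme_profile(g, "Firmicutes"), "unknown phylum")
})

test_that("a phylum planted at 14.5% of total CAZyme RPKM reports 0.145", {
  info <- data.frame(gene_id = c("a1", "b1"),
                     phylum = c("Actinobacteria", "Proteobacteria"),
                     cazy_class = "GH", cazy_family = NA, func_gene = NA,
                     substrate_group = NA, length_bp = 1000)
  counts <- matrix(c(145, 855), 2, 1,
                   dimnames = list(info$gene_id, "s1"))
  g <- gene_table(info, counts, sample_totals = c(s1 = 1e6))
  prof <- phylum_cazyme_profile(g, c("Actinobacteria", "Proteobacteria"),
                                denominator = "table")
  expect_equal(sum(prof$shares["Actinobacteria", ]), 0.145,
               tolerance = 1e-9)
})

test_that("equal class RPKM across two phyla splits shares evenly", {
  info <- data.frame(gene_id = c("a1", "b1"), phylum = c("P1", "P2"),
                     cazy_class = "GH", cazy_family = NA, func_gene = NA,
                     substrate_group = NA, length_bp = c(1000, 2000))
  counts <- matrix(c(100, 200), 2, 1, dimnames = list(info$gene_id, "s1"))
  g <- gene_table(info, counts, sample_totals = c(s1 = 1e6))
  prof <- phylum_cazyme_profile(g, c("P1", "P2"))
  expect_equal(unname(prof$shares[, "GH"]), c(0.5, 0.5))
})

test_that("the average-CAZyme ratio divides shares elementwise", {
  expect_equal(unname(average_cazyme_ratio(c(A = 0.2), c(A = 0.1))), 2)
  # the focal-phylum situation: 16% of CAZymes from 4.6% of cells
  expect_equal(unname(average_cazyme_ratio(c(Actinobacteria = 0.16),
                                           c(Actinobacteria = 0.046))),
               0.16 / 0.046, tolerance = 1e-12)
  sh <- c(A = 0.3, B = 0.7)
  expect_equal(unname(average_cazyme_ratio(sh, sh)), c(1, 1))
  # scale-free in the numerator source: shares, not raw RPKM, enter
  expect_error(average_cazyme_ratio(c(A = 0.2), c(A = 0)), "zero")
  expect_error(average_cazyme_ratio(c(A = 0.2), c(B = 0.5)), "no taxonomic")
})

test_that("variation profiles equal the brute-force Z-score-then-SD oracle", {
  shares <- array(0, dim = c(2, 2, 4),
                  dimnames = list(c("P1", "P2"), c("GH", "GT"),
                                  c("1", "2", "4", "8")))
  shares["P1", "GH", ] <- c(0.1, 0.1, 0.1, 0.1)
  shares["P2", "GH", ] <- c(0.05, 0.15, 0.05, 0.15)
  shares["P1", "GT", ] <- c(0.2, 0.25, 0.3, 0.35)
  shares["P2", "GT", ] <- c(0.4, 0.3, 0.2, 0.1)
  prof <- structure(list(shares = shares, rpkm = shares,
                         denominator = "class", by = "stage",
                         features = c("GH", "GT"), phyla = c("P1", "P2"),
                         normalization = "rpkm"),
                    class = "cazyme_profile")
  v <- variation_profile(prof)
  for (f in c("GH", "GT")) {
    expect_equal(v$sd[, f], oracle_zscore_sd(shares[, f, ]),
                 tolerance = 1e-10)
  }
  # a stage-invariant series has zero variation; the oscillating one more
  expect_equal(unname(v$sd["P1", "GH"]), 0)
  expect_lt(v$sd["P1", "GH"], v$sd["P2", "GH"])
  expect_equal(v$mean_variation, rowMeans(v$sd))
})

test_that("substrate-group roll-ups conserve RPKM mass", {
  tr <- simulation_truth(seed = 91)
  g <- rpkm_normalize(simulate_gene_table(tr))
  ro <- substrate_group_rollup(g)
  func_mass <- sum(g$abundance[!is.na(g$info$func_gene), ])
  expect_equal(sum(ro$rpkm), func_mass, tolerance = 1e-9 * func_mass)
  expect_identical(ro$features, SUBSTRATE_GROUPS)

  # brute-force per-gene summation for one phylum and group
  map <- functional_gene_catalog()
  sel <- !is.na(g$info$func_gene) & g$info$phylum == "Actinobacteria" &
    map$substrate_group[match(g$info$func_gene, map$func_gene)] ==
    "cellulose"
  expect_equal(unname(ro$rpkm["Actinobacteria", "cellulose"]),
               sum(g$abundance[sel, ]), tolerance = 1e-10)

  # single-group mapping: the group total equals the table total and the
  # empty groups stay as explicit zero rows
  map_one <- data.frame(func_gene = map$func_gene,
                        substrate_group = "lignin")
  ro_one <- substrate_group_rollup(g, mapping = map_one)
  expect_equal(sum(ro_one$rpkm["Actinobacteria", ]),
               sum(ro_one$rpkm["Actinobacteria", "lignin"]))
  expect_true(all(ro_one$rpkm[, "cellulose"] == 0))

  bad_map <- map[-1, ]
  expect_error(substrate_group_rollup(g, mapping = bad_map),
               map$func_gene[1])
})

test_that("fertility contrasts compare log shares between soil classes", {
  x <- matrix(c(rep(0.1, 4), rep(0.1, 4)), 1,
              dimnames = list("GH", paste0("s", 1:8)))
  fert <- rep(c("high", "low"), each = 4)
  res <- fertility_contrast(x, fert)
  expect_equal(res$p_value, 1)
  expect_equal(res$mean_high, res$mean_low)

  # log transform preserves the ordering of strictly positive group means
  withr::with_seed(92, {
    y <- rbind(GH = c(rlnorm(4, log(0.1), 0.1), rlnorm(4, log(0.3), 0.1)))
    colnames(y) <- paste0("s", 1:8)
    r1 <- fertility_contrast(y, fert, log_transform = TRUE)
    r2 <- fertility_contrast(y, fert, log_transform = FALSE)
    expect_equal(sign(r1$mean_high - r1$mean_low),
                 sign(r2$mean_high - r2$mean_low))
  })
  expect_error(fertility_contrast(x, rep("high", 8)), "at least 3")
})
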