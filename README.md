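# strawdecomp

Statistical toolkit for plant-residue (straw) decomposition microbiome
studies. It implements the inference chain used to argue that a
numerically minor taxonomic group — typically *Actinobacteria* — plays a
disproportionate, stable role in straw degradation:

* **Distance-decay slope contrasts.** Pairwise community similarity
  (1 − Bray-Curtis) is regressed on pairwise straw-chemistry distance
  (standardized Euclidean over cellulose, hemicellulose, lignin and
  water-soluble polysaccharides). For samples *i*, *j* with within-group
  similarity *S(i,j)* and chemistry distance *D(i,j)*, the fit is
  `S = a + b·D` over all n(n−1)/2 pairs; groups with flatter (less
  negative) slope *b* are compositionally stabler along decomposition.
  Slope sign and focal-vs-other slope differences are tested by
  permutation (taxon reassignment by default; Mantel-style label
  permutation for the sign test), since the pairs are not independent.
* **RMT co-occurrence networks.** Taxon correlation matrices are
  thresholded where the eigenvalue nearest-neighbor spacing distribution
  transitions from GOE (Wigner surmise, `P(d) = (πd/2)·exp(−πd²/4)`) to
  Poisson (`P(d) = exp(−d)`) statistics, the random-matrix-theory
  criterion for having stripped noise. The signed network yields
  topology indices (average degree 2E/N, transitivity, geodesic
  efficiency, greedy Newman-Girvan modularity) and the positive/negative
  accounting of links between a focal lineage and all other members.
* **CAZyme attribution.** RPKM-normalized, taxonomically assigned gene
  tables give per-phylum CAZy-class profiles (GH, GT, PL, CE, CBM, AA),
  the average-CAZyme ratio (CAZyme share / taxonomic abundance share),
  Z-score SD variation of shares across decomposition stages,
  substrate-group roll-ups of 44 functional genes, and Welch-t
  fertility contrasts on log shares.
* **Synthetic study generator.** All inputs — declining chemistry
  trajectories, Gaussian-niche communities with planted slope orderings,
  block-correlated OTU tables with planted modules and mixed links, and
  gene tables with planted fertility effects — can be simulated with
  known ground truth under a single seed (3 sites × 5 stages × 12
  replicates by default), so the full pipeline is testable without any
  sequencing data.

Everything is plain R with `vegan` and `igraph` behind the standard
steps; all permutation tests take an explicit seed and are exactly
reproducible.

## Worked example

```r
library(strawdecomp)

bundle <- simulate_study(simulation_truth(seed = 7), scale = "ci")
res <- run_study_pipeline(bundle, n_perm = 199, seed = 7)

print(res$slopes)
#> slope_panel (focal: Actinobacteria)
#>   Acidobacteria        slope  -0.1358  r2 0.906  p(slope<0) 0.005
#>   Actinobacteria       slope  -0.1376  r2 0.861  p(slope<0) 0.005
#>   Bacteroidetes        slope  -0.1967  r2 0.719  p(slope<0) 0.005
#>   Firmicutes           slope  -0.1955  r2 0.790  p(slope<0) 0.005
#>   Proteobacteria       slope  -0.1833  r2 0.637  p(slope<0) 0.005
#>   Actinobacteria vs Acidobacteria  delta  -0.0018  p 0.955
#>   Actinobacteria vs Bacteroidetes  delta   0.0591  p 0.08
#>   Actinobacteria vs Firmicutes     delta   0.0579  p 0.015
#>   Actinobacteria vs Proteobacteria delta   0.0457  p 0.09

print(res$links)
#> link_accounting (Actinobacteria): 362 of 899 links mixed (40.3%);
#>   +120 (13.3%), -242 (26.9%)

round(res$cazyme_ratio, 2)
#>  Acidobacteria Actinobacteria  Bacteroidetes     Firmicutes Proteobacteria
#>           1.01           4.12           1.10           0.86           0.65
```

Reading the output: every phylum's similarity decays significantly with
chemistry distance (all slopes negative, permutation p = 0.005 at 199
permutations), but the two broad-niche groups planted by the generator
(Actinobacteria, Acidobacteria) decay flattest — the focal contrast is
significant against Firmicutes and indistinguishable from Acidobacteria,
exactly the planted ordering. In the co-occurrence network, 40% of links
connect Actinobacteria to other members, negative links dominating. The
average-CAZyme ratio shows the planted asymmetry: Actinobacteria hold
≈ 4× more CAZyme abundance than their ~5% community share would suggest,
while the dominant phyla sit near or below 1.

Single stages are available as plain functions (`bray_curtis`,
`chemistry_distance`, `mantel_test`, `permanova`, `distance_decay_fit`,
`slope_contrast_test`, `correlation_matrix`, `select_rmt_threshold`,
`build_network`, `topology_metrics`, `intergroup_links`,
`rpkm_normalize`, `phylum_cazyme_profile`, `variation_profile`,
`substrate_group_rollup`, `fertility_contrast`, …), and a thin CLI wraps
the common flows:

```sh
Rscript inst/scripts/strawdecomp-cli.R simulate --seed 7 --scale ci --out study/
Rscript inst/scripts/strawdecomp-cli.R pipeline --seed 7 --scale ci --n-perm 199 --out results/
```

See `vignettes/strawdecomp-methods.Rmd` for the models, parameter
choices, numerical conventions and limitations.

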