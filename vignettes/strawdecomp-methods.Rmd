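---
title: "Methods: distance decay, RMT networks and CAZyme attribution in straw-decomposition microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance decay, RMT networks and CAZyme attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawdecomp)
```

# The scientific setting

When crop straw decomposes in soil, the bacterial consortia colonizing it
turn over as the substrate chemistry changes: labile water-soluble
polysaccharides disappear first, then hemicellulose and cellulose, while
lignin persists. A recurring observation in such systems is that some
taxonomic groups — notably *Actinobacteria* — remain compositionally and
functionally stable across this succession despite being numerically
minor, while holding a disproportionate share of the community's
carbohydrate-active enzymes (CAZymes). `strawdecomp` implements the
statistical chain used to quantify that claim:

1. **Distance-decay contrasts** — how fast does within-group community
   similarity decay as straw chemistry diverges, and is the focal group's
   decay slope flatter than other groups'?
2. **RMT co-occurrence networks** — a signed correlation network whose
   threshold is chosen by random-matrix theory, with topology indices and
   an accounting of links between the focal group and everyone else.
3. **CAZyme attribution** — RPKM-normalized, taxonomically assigned gene
   abundances rolled into per-phylum CAZy-class profiles, abundance-
   normalized "average CAZyme" ratios, stage-to-stage variation, and
   contrasts between soils of different fertility.

A synthetic-data generator with fully known ground truth stands in for
the field and stable-isotope-probing (SIP) sequencing data, so every
stage is testable end to end.

# Distance matrices

Community dissimilarity is Bray-Curtis on relative abundances,
$BC(i,j) = \sum_t |x_{ti} - x_{tj}| / \sum_t (x_{ti} + x_{tj})$,
computed with `vegan::vegdist`. Straw chemistry distance is Euclidean
over the four measured components (cellulose, hemicellulose, lignin,
WSP, all mass fractions of dry straw). Because the components live on
different scales, each is z-standardized across samples by default; a
`standardize = FALSE` flag preserves the raw-scale alternative, and a
zero-variance component is dropped with a warning rather than producing
0/0.

Counts are rarefied to a common depth before any of this. Rarefaction is
a multivariate hypergeometric draw — sampling reads *without*
replacement — which matches the semantics of subsampling an observed
read pool once; it is seeded and exactly reproducible.

Per-phylum analyses use lineage subsets of the relative-abundance table.
Two subset modes exist on purpose: *renormalized* columns (re-closed to
sum 1) for comparing within-group composition across samples, and
*unrenormalized* fractions for attribution denominators, where the
subset's share of the whole community is the quantity of interest.
Unassigned ranks aggregate into `unclassified:<parent>` labels so that
per-sample mass is conserved exactly.

# Matrix-level inference

The Mantel test correlates the upper triangles of two distance matrices
and permutes the sample labels of the second matrix jointly over rows
and columns; PERMANOVA partitions the total sum of squared distances
into between- and within-group components (one-way design) and permutes
group labels. Both are implemented in-package so a single integer seed
controls every permutation stream and so degenerate inputs have defined
behavior (perfect group separation reports an `Inf` pseudo-F sentinel).
Unit tests pin the Mantel statistic to `vegan::mantel` and the pseudo-F
to `vegan::adonis2` and to an independent brute-force enumeration.

All permutation p-values use the $(1+b)/(1+m)$ convention, so p is never
0 and has resolution $1/(m+1)$. Repeated pairwise PERMANOVA calls are not
multiplicity-corrected; the result object carries `correction = "none"`
to make that explicit.

# Distance-decay regression and the slope contrast

The distance-decay fit regresses pairwise community **similarity**
($1 - BC$) on pairwise chemistry distance over all $n(n-1)/2$ unordered
pairs, matching the axes on which such panels are conventionally drawn;
a flag switches to dissimilarity. Pairs sharing a sample are not
independent, so no analytical standard errors are reported — inference
is purely permutational. The slope-sign test permutes the community
matrix's labels (Mantel-style) and is one-tailed for negative slope.

The headline statistic is the **slope contrast**: is the focal group's
slope flatter (closer to zero) than another group's? The observed
statistic is $\Delta = b_a - b_b$ (absolute for the two-sided test). The
choice of permutation null deserves care, and the package ships three
schemes:

* `taxon_shuffle` (default) pools the taxa of both groups and reassigns
  them at random to two pseudo-groups of the original sizes,
  recomputing distances and slopes each time. Under the null that the
  two groups share one turnover process, taxa are the exchangeable
  unit, and this scheme absorbs both sample-level noise and the
  between-group variability that comes from each group holding a
  finite, random draw of taxa. In null simulations under the package's
  own generator (identical niche breadths, 150 replicates) its type-I
  error at $\alpha = 0.05$ was 0.06 — consistent with nominal — and it
  retains ~95% one-sided power against a 2-fold niche-breadth gap at 30
  samples.
* `sample_swap` exchanges a sample's group-a and group-b profiles
  independently per sample, on the padded union taxon space. It
  preserves within-sample dependence but cannot absorb realized
  taxon-set differences between groups, and cross-provenance pairs
  saturate at Bray-Curtis 1; measured type-I error was ~0.5.
* `pair_label` flips the a/b assignment of each (distance, similarity)
  pair independently. It is the cheapest but ignores the within-sample
  dependence among pairs entirely; measured type-I error was ~0.7.

The two swap-style schemes are retained for comparability and for
settings where only distance matrices are available (`pair_label`), but
calibrated inference should use `taxon_shuffle`. Directional claims
("flatter than") use `alternative = "greater"`.

`slope_panel()` orchestrates one fit per group plus one contrast per
(focal, other) pair, with per-group seeds derived deterministically from
the master seed and groups processed in alphabetical order.

A scope note: regional-scale fits pool all samples' pairs into a single
regression rather than averaging within-site fits — the panel layout
this mirrors pools sites the same way.

# The RMT co-occurrence network

Taxa observed in at least half the samples (configurable) are correlated
pairwise (Pearson by default; Spearman and a log transform with a
half-minimum pseudocount are options). The network threshold is not
hand-picked: for each candidate threshold, entries with $|r|$ below it
are zeroed and the eigenvalue spectrum of the surviving matrix is
examined. Random-matrix theory predicts that noise-dominated symmetric
matrices show Gaussian-orthogonal-ensemble (GOE) spacing statistics —
the Wigner surmise $P(d) = (\pi d/2)\,e^{-\pi d^2/4}$ — while systems
reduced to independent blocks show Poisson spacings $P(d) = e^{-d}$. The
selected threshold is the smallest grid value whose nearest-neighbor
spacing distribution (NNSD) conforms to Poisson (chi-square p > 0.05),
i.e. the point where random structure has just been removed.

Numerical conventions in the scan:

* Eigenvalues are *unfolded* by a smoothing-spline fit (default 10 df)
  to the empirical cumulative spectral density, made monotone by a
  running maximum, so that the mean spacing is 1 within ±0.05.
* Taxa left with no surviving off-diagonal entry at a threshold are
  dropped before the eigendecomposition — they are isolated nodes and
  would contribute exact eigenvalue-1 degeneracies.
* Remaining tied eigenvalues (within 1e-10) are collapsed so spacings
  stay strictly positive.
* The chi-square uses bins of width 0.2 on [0, 3] plus an open tail
  bin, merged until every expected count is at least 5, with a
  Kolmogorov-Smirnov fallback when fewer than 5 usable bins remain.
* Thresholds where fewer than 20 connected taxa survive are recorded as
  non-evaluable rather than aborting the scan; if no threshold
  qualifies, the error object carries the full scan for audit.

Edges keep ties at the boundary ($|r| \ge$ threshold) and are signed by
the correlation sign. Topology indices follow the usual conventions:
average degree $2E/N$; global transitivity (3 × triangles / connected
triples, signs ignored); geodesic efficiency as the mean over ordered
pairs of inverse shortest-path length with unreachable pairs
contributing zero (recorded in the output, since conventions differ);
harmonic geodesic distance as its reciprocal; and Newman-Girvan
modularity of a deterministic greedy (fast-greedy) partition —
stochastic annealing maximizers are deliberately out of scope so runs
are reproducible. Node "size" (mean relative abundance) is stored as
visualization metadata only.

`intergroup_links()` counts edges with exactly one endpoint in the focal
lineage, split by sign, as fractions of all links — the quantity used to
argue that interactions between the focal group and the rest of the
community intensify in less fertile soil.

# CAZyme attribution

Gene abundances are RPKM: count / (length in kb) / (mapped reads in
millions). Per-phylum CAZy-class profiles sum RPKM per (phylum, class)
and normalize either within each class across the listed phyla
("what fraction of the GH pool does this phylum hold", the default) or
against the whole table. The listed dominant phyla form the denominator,
matching the framing "of the total CAZymes encoded by the dominant
phyla"; a whole-community denominator is a flag away. Whether profiles
pool all samples or stay per stage is selectable (`by =`); pooled is the
default reading.

The **average-CAZyme ratio** divides a phylum's CAZyme share by its
taxonomic abundance share. It is scale-free in both numerator and
denominator and is the number that makes a non-dominant, enzyme-rich
group visible: a few percent of the community holding ~15% of the
CAZymes yields a ratio well above most dominant phyla.

**Variation profiles** quantify stability across decomposition stages:
per feature (CAZy class or substrate group) the phylum × stage panel of
shares is Z-scored — over the pooled panel by default, so phyla share
one scale; a per-phylum scope is available and recorded in the output —
and each phylum's variation is the SD of its own Z-scored stage series.
Low values mark groups whose functional repertoire is stable through
succession.

The 44 plant-residue-decomposition functional genes roll up into four
substrate groups (cellulose, hemicellulose, lignin,
cello-oligosaccharides degradation). The packaged catalog
(`inst/extdata/functional_genes_synthetic.tsv`) is a curated synthetic
stand-in with plausible gene symbols; ids are opaque strings throughout,
so any catalog with columns `func_gene`, `substrate_group` can be
substituted. Roll-ups conserve total RPKM and keep empty groups as
explicit zero rows.

**Fertility contrasts** compare per-feature shares between high- and
low-fertility samples with a Welch two-sample t test on natural-log
shares (zeros shifted by half the smallest nonzero value). Welch rather
than a pooled-variance test because variance heterogeneity between soils
is expected; significance stars use the conventional 0.05/0.01 cutoffs.

# The synthetic study generator

Every generator is a pure function of (parameters, seed): identical
inputs are bit-identical, and each dataset can be accompanied by its
serialized `simulation_truth`. The default design mirrors the emulated
field study: 3 sites × stages 1, 2, 4, 8, 16 weeks × 12 replicates,
8000 reads per sample, with one fertile site (CS), one infertile (YT)
and one unclassified (CQ). A `scale = "ci"` profile shrinks replicates
and depth 4-fold; that profile (45 samples, depth 2000) is what the
test suite and the bundled acceptance script run, and the problem sizes
quoted below are its sizes.

**Chemistry** decays exponentially per component with site-specific
rates (defaults: cellulose 0.060/wk, hemicellulose 0.070/wk, lignin
0.012/wk, WSP 0.120/wk; site multipliers 0.9/1.1/0.8) from a typical
straw composition (38/30/18/8% of dry mass), with 5% lognormal
replicate noise. These are realistic magnitudes for 16-week straw
litter decay, chosen once; regression on the simulated trajectories
recovers the planted rates within 10%.

**Communities** place each sample on a latent gradient — the first
principal coordinate of its standardized chemistry — and give every
taxon a Gaussian response with group-specific niche breadth
$\sigma_g$. Narrow niches turn over quickly along the gradient, so the
planted ordering of $\sigma$ maps onto a planted ordering of
distance-decay slopes; this is deliberately an *ordering* guarantee,
not an exact-slope guarantee, because arbitrary pairwise-similarity
targets are not jointly realizable. Defaults make the focal
Actinobacteria and Acidobacteria the broad-niche (flat) groups. Each
group's expected whole-community share is planted too (Actinobacteria
4.6%, the dominant groups 20–35%), so the focal group is numerically
minor exactly as in the motivating system. Counts are multinomial at
the configured depth.

**Correlated OTUs** for the network branch come from a latent Gaussian
factor model: block covariance with within-module correlation
`within_r` (default 0.8, five modules of twelve taxa), mapped to
abundances by $\exp(0.1 z)$ and closed to relative abundances. The mild
exponent matters: a steeper monotone transform attenuates negative
correlations asymmetrically (an analytic property of lognormals), which
would push planted −0.9 pairs below a 0.8 edge threshold. Mixed links
are planted by rewiring selected non-focal taxa to correlate at
±`mixed_r` with focal partners (defaults: 10 positive, 20 negative —
negative links dominating, as observed in infertile-soil networks).
One caveat is intrinsic: closing five equal blocks to compositions
forces ≈ −0.2 correlations *between* modules, so with few samples the
empirical between-module noise spreads above the nominal 0.2 bound.
Recovery tests therefore use a long sample axis (400–1500 samples) so
the realized noise respects the planted bound, while the pipeline
default keeps the study-like 60 samples — and its denser, noisier
network is the honest consequence.

**Gene tables** draw per-phylum CAZy-class compositions from a
Dirichlet around a common profile, lognormal gene lengths within
300–3000 bp, and negative-binomial counts (dispersion 0.3, typical
metagenomic overdispersion) around RPKM-consistent means, plus 10%
lognormal sample noise. Low-fertility samples multiply the focal
phylum's configured classes (GH/GT/CE by default) by the planted fold
change (default 2), reproducing the "more focal CAZymes in poorer
soil" signal.

# What the tests do and do not show

The test suite asserts: exact agreement of every core statistic with
independent brute-force oracles (≤ 1e-10); nominal type-I error of the
Mantel, slope-sign, slope-contrast and fertility tests over 500 null
replicates of 999 permutations each (n = 20 samples for the
distance-based nulls); ≥ 95% recovery of the planted slope ordering and
≥ 80% one-sided contrast power at a 2× niche-breadth gap (30 samples,
depth 8000); correct Poisson/GOE discrimination of the NNSD machinery
and exact recovery of planted modules and mixed-link counts; and
bit-identical end-to-end runs under equal seeds.

What passing these tests does *not* show: the generator produces
compositionally simple, well-mixed communities — no spatial structure
within sites, no phylogenetic correlation of niches, no
sequencing-error or chimera artifacts, no compositional bias between
taxa, and gene tables with clean taxonomic assignment. Real amplicon
and shotgun data violate all of these. In particular, Pearson
correlations on closed compositions are known to carry negative bias
(the package surfaces this but deliberately does not implement
SparCC-style corrections), and the RMT threshold on small real studies
(tens of samples) tends to sit at the low end of the grid, yielding
dense networks. Conclusions about real straw microbiomes still require
the usual domain scrutiny; what the package guarantees is that the
statistics it reports are the statistics it defines.

# Known limitations

* One-way designs only for PERMANOVA; no nested/stratified permutation.
* Greedy modularity has the usual resolution limit; very small modules
  connected by noise bridges can merge.
* The NNSD chi-square needs a few hundred spacings to be decisive;
  matrices much smaller than ~50 connected taxa give weak scans.
* `sample_swap` and `pair_label` are approximations retained for
  comparability; their miscalibration under taxon-sampling variability
  is documented above and in the function help.
* The packaged functional-gene catalog is a synthetic stand-in, not a
  community-standard reference.
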