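---
title: "Integrating GWAS with QTL likelihood intervals in structured inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating GWAS with QTL likelihood intervals in structured inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasqtl)
```

## The problem

Linkage (QTL) mapping in biparental crosses and genome-wide association
studies (GWAS) in diversity panels interrogate the same biology with
complementary blind spots: QTL likelihood intervals are unbiased by allele
frequency but span megabases; association peaks are narrow but miss rare
alleles and are vulnerable to population structure.  `gwasqtl` implements a
pipeline for combining the two, developed around seed-size genetics in a
sorghum association panel (354 inbred accessions, 265,487
genotyping-by-sequencing SNPs) and the body of published sorghum and rice
seed-size QTL: a structure-aware mixed-model scan, LD-based significance
thresholds and hotspot calling, physical anchoring of likelihood intervals,
and exact enrichment tests for QTL-GWAS colocalization within a genome and
for trait-locus correspondence across genomes over collinear orthologs.

Because the original panel genotypes are not redistributable, the package
carries a first-class synthetic-data module that emulates the panel's
statistical structure, so the entire pipeline is testable end-to-end with
no external data.

## The association model

The scan fits, for each SNP $j$,

$$ y = \mu + P\alpha + g_j\beta_j + u + e, \qquad
   u \sim N(0, K\sigma_g^2), \quad e \sim N(0, I\sigma_e^2), $$

where $P$ holds the leading principal components of the standardized
genotype matrix (fixed effects for population structure), $K$ is the
VanRaden marker-based kinship matrix (random polygenic effects), and
$\beta_j$ is the allele-dosage effect tested by a Wald $t$-test.  Variance
components are estimated once by restricted maximum likelihood under the
no-marker null model via the spectral decomposition of $K$ (the standard
P3D/EMMAX-style computation) and reused across markers; exact per-marker
REML is available as `variance_component_mode = "per_marker"` for small
data.  Setting the compression option replaces individuals by
average-linkage kinship clusters (the compressed mixed linear model);
`compression_groups = "auto"` scans powers of two and keeps the null-model
REML maximizer, and compression with one group per individual reproduces
the uncompressed scan exactly.

Two limiting behaviours anchor correctness: with identity kinship (or
$\hat\sigma_g^2 = 0$) and no covariates the per-marker $p$-values equal
ordinary least-squares $p$-values, and under a structured global null the
empirical type-I error at $\alpha = 0.01$ stays within $[0.005, 0.02]$
while naive single-marker regression on the same data exceeds 0.05 by an
order of magnitude.  Both are asserted in the test suite.

Default filters follow standard association-mapping practice: SNPs with
minor-allele frequency below 0.05 (rare variants, for which the panel has
poor power) or missingness above 0.2 are excluded from the scan.  Missing
calls are mean-imputed inside kinship, PCA, and LD computations only; raw
genotypes are never modified.

## Significance thresholds and hotspots

Two multiple-testing rules are provided.  The Bonferroni cutoff is
$\alpha/m$; for $\alpha = 0.05$ and $m = 265{,}487$ tests this is
$1.88\times10^{-7}$.  The LD-bin correction replaces $m$ by the effective
number of independent tests, defined as genome size divided by average LD
extent; with a 730 Mb genome and the 150 kb distance at which mean
$r^2$ decays below the background level 0.1, this gives 4866.67 effective
tests and a cutoff of about $1.03\times10^{-5}$ — within an order of
magnitude of $10^{-5}$, whose nearest power of ten is reported alongside.
The effective count is deliberately kept real-valued rather than rounded.

An association hotspot is called from a *seed* SNP with $p \le 10^{-5}$
that is linked at $r^2 \ge 0.5$ to at least 10 *minor significant* SNPs
($10^{-5} < p \le 10^{-3}$); the span of the seed and its linked minors
sets the hotspot boundary.  Both threshold comparisons are inclusive.
Design choices the rule itself leaves open:

* **Seed-centric linkage.** $r^2$ is measured seed-to-minor, not
  minor-to-minor; chaining through minors is available behind
  `hotspot_config()` if a broader rule is wanted.
* **Merging.** Seeds sharing a linked minor, or whose member spans
  overlap, merge into one hotspot (union of members), since hotspots are
  reported at region level.  Merging runs to a fixed point.
* **Search window.** Minor SNPs are sought within `max_link_dist_bp`
  (default 2 Mb) of the seed, bounding the quadratic LD search; set it to
  chromosome length for an unbounded search.
* **Genome-wide calling.** Hotspots are called wherever the rule fires,
  not only inside known QTL intervals — an association region without
  linkage support is a legitimate (and interesting) outcome.

`detect_hotspots()` is verified against a brute-force oracle (enumerate
every seed, recompute every seed-minor $r^2$ directly, merge by the same
rule) with exact set equality on hundreds of random instances.

All LD statistics use composite (genotype-correlation) $r^2$ — the squared
Pearson correlation of allele-count vectors — which for highly inbred,
essentially homozygous material coincides with haplotype $r^2$ and needs
no phasing.  The same statistic is used consistently by the decay
estimator, the regional matrices, and hotspot linkage.

## Interval anchoring and algebra

QTL likelihood intervals from linkage studies are anchored to physical
coordinates by the flanking-marker rule: markers of the peak's linkage
group are ordered by genetic position and scanned outward from the
likelihood peak; the first marker on each side with physical alignment
information sets the bound.  An aligned peak may stand in for a side with
no aligned marker beyond it; otherwise the interval is flagged one-sided
and extends to the chromosome end.  Flanking aligned markers on different
chromosomes raise a "discordant anchoring" error rather than a silent
guess.

All coordinates are 1-based inclusive internally (genome-browser
convention); only BED I/O converts.  Interval overlap is
$\max(0, \min(\text{ends}) - \max(\text{starts}) + 1)$, so touching
intervals are disjoint; `merge_intervals()` unions only intervals sharing
at least 1 bp (via `GenomicRanges::reduce` with zero gap width) and is
idempotent.  The refinement ratio — QTL length over co-localized hotspot
length — quantifies the map-resolution gain of association evidence over
linkage evidence.

## Enrichment tests

`fisher_exact()` computes exact hypergeometric probabilities in log space
over the full support fixed by the 2x2 margins.  One-sided enrichment is
$P(A \ge a)$; the two-sided value uses the point-probability method (sum
of all outcome probabilities not exceeding the observed one, with a
$10^{-7}$ relative tie tolerance, matching standard practice).  A zero
margin yields a degenerate result with $p = 1$ and a flag rather than an
error.  Exactness is asserted against an independent `lchoose`-based
enumeration (max $|\Delta p| < 10^{-12}$) and cross-checked against
`stats::fisher.test`, which is never the implementation.

Three constructions feed it:

1. **GWAS x QTL within a genome.**  Every *tested* SNP (the scan output —
   only tested loci can be association loci) is classified by significance
   at the hotspot seed level and by position inside the merged QTL
   intervals.
2. **Association region x foreign QTL across taxa.**  The universe is the
   collinear ortholog pairs on the stated orthologous chromosome pair;
   each pair is classified by membership of its A-gene in the association
   region and its B-gene in the merged foreign intervals.  Gene membership
   is midpoint containment by default (no double counting of
   boundary-straddling genes); any-overlap is available via the
   `membership` argument.  A per-hotspot battery reports
   Benjamini-Hochberg adjusted $p$-values alongside the raw ones.
3. **QTL x QTL across taxa.**  Each A-interval is projected through the
   ortholog pairs it contains (span of partner-gene midpoints, per
   B-chromosome) and classified as within/outside the merged B intervals.
   The chance expectation is estimated by tiling the projection universe
   into bins at the median projected-interval length and classifying each
   bin by whether its *midpoint* is covered — an unbiased,
   length-proportional coverage sample — and the within/outside counts are
   compared to the covered/uncovered bin counts by the same exact test.
   A-intervals containing no ortholog-bearing genes are excluded and
   counted.

## The synthetic panel generator

`simulate_population()` emulates the statistical features the analyses
rely on, not sequence-level realism:

* **Structure.**  Accessions are split into `n_subpops` groups whose
  allele frequencies diverge from common ancestral frequencies under a
  Balding-Nichols model with parameter `fst_like_divergence`.  The default
  0.2 was chosen once as representative of the strong racial
  differentiation in sorghum diversity panels (K-means on two principal
  components recovers the groups essentially perfectly at that level, as
  it does in the real panel).
* **LD.**  Each chromosome is tiled into haplotype blocks of
  `ld_block_len_bp` (default 150 kb, the panel's genome-average LD
  extent), lengthened 10-fold across a central 40% span to mimic
  suppressed pericentromeric recombination.  Within a block, 2-8 founder
  haplotypes per subpopulation carry a *core founder partition*; each SNP
  either copies that partition with a per-SNP founder-flip probability
  drawn uniformly up to `core_decay_max` (probability `ld_tightness`,
  default 0.9) or segregates independently.  This produces a realistic
  continuous spectrum of within-block $r^2$ and makes the mean $r^2$
  decay curve drop below background at the block length.  Blocks are
  independent given subpopulation (`block_recomb_prob = 1` by default;
  lower values carry founder assignments across adjacent blocks).
* **Inbreeding.**  Accessions draw the same founder haplotype for both
  gametes with probability `inbreeding_rate` (default 0.98) — selfed lines
  are homozygous for whole haplotypes, which is what preserves long-range
  LD — and residual heterozygotes are additionally collapsed per locus at
  the same rate.
* **Planted QTL.**  A requested (chromosome, position, effect, frequency)
  is attached to the nearest simulated SNP (an error if none lies within
  half a block length), which becomes an exact copy of its block's core
  partition with the partition's carrier count pinned to approximate the
  requested frequency (granularity one founder).  Planting happens before
  genotypes are drawn, so block-mates are genuinely in LD with the causal
  SNP — the property hotspot detection exercises.
* **Phenotypes.**  Trait values are planted additive effects plus an
  optional genome-wide polygenic value plus environment-specific Gaussian
  noise scaled so that the per-observation genetic variance fraction
  equals `target_h2` (default 0.31, the seed-mass repeatability regime);
  `env_sd_multipliers` modulate per-environment noise.  With no genetic
  variance the trait is pure unit noise.
* **MAF floor.**  SNPs whose realized minor-allele frequency falls below
  `maf_floor` (default 0.05) are dropped after generation (planted causal
  SNPs exempt), so `n_snps` is the pre-filter request.

All randomness flows from `rng_seed` through an isolated RNG scope; the
caller's RNG state is never touched, and equal seeds give byte-identical
output.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: genotyping error and call-rate structure,
allele-frequency spectra shaped by demography and selection, admixed or
clinal (rather than discrete) structure, LD that decays smoothly within
blocks rather than by block membership, genotype-by-environment
interaction beyond noise-variance scaling, and any sequence-level feature.
Results on real panels additionally depend on phenotype quality and on the
provenance of the compiled QTL intervals.

## Numerical choices

* REML in $\lambda = \sigma_g^2/\sigma_e^2$ is profiled on a 49-point
  grid over $\log\lambda \in [-12, 12]$ and refined by golden-section
  search in the bracketing interval; $\lambda$ at the lower boundary is
  truncated to exactly 0, which makes the OLS reduction exact rather than
  approximate.
* A kinship matrix that is not positive semidefinite (possible after
  compression averaging) is repaired by inflating the diagonal by the most
  negative eigenvalue plus $10^{-10}$, with a message.
* Markers whose design is singular (collinear with covariates,
  monomorphic after subsetting) are reported with missing $p$ rather than
  dropped silently; scan output excludes only MAF/missingness-filtered
  SNPs.
* Threshold ties: both hotspot comparisons are inclusive ($\le$), so a
  SNP at exactly $10^{-5}$ is a seed, and one at exactly $10^{-3}$ is a
  minor.
* Degenerate 2x2 tables (any zero margin) return $p = 1$ with a flag.
* Calibration of the overlap test is checked on the randomized upper-tail
  $p$-value $u = P(A > a) + U\,P(A = a)$, which is exactly uniform if and
  only if the implemented tail probability is exact; the raw $p$ of a
  discrete exact test is necessarily super-uniform (conservative), which
  is asserted separately.  A Kolmogorov-Smirnov test on the raw $p$ would
  reject for reasons inherent to discreteness, not implementation error.
* Published threshold arithmetic: $0.05/265{,}487 = 1.8833\times10^{-7}$,
  conventionally quoted as $1.89\times10^{-7}$; the package returns the
  exact value.

## Problem sizes used by the test suite and acceptance script

Simulation sizes were chosen as the smallest that leave the monitored
statistics comfortably inside their tolerance bands: unit tests use panels
of 30-300 accessions and 60-2,500 SNPs; the structured-null type-I check
uses 400 accessions x ~2,300 tested SNPs; parameter-recovery checks
average 20 replicates of a 354-accession panel (450 SNPs for the
three-SNP 54% PVE regime, 300 SNPs x 3 environments for the 0.31
repeatability regime); and the end-to-end positive/null controls use a
354-accession, 10-chromosome, 30,000-SNP genome with three planted QTL of
equal effect (combined $h^2 = 0.3$, causal allele frequency 0.3).  At that
size the hotspot chain detects at least one planted hotspot in roughly
nine of ten replicates, so the positive control is replicated up to three
times (overall failure probability about $10^{-3}$); the global-null
control runs the identical chain without planted effects 20 times and
requires silence in at least 95% of runs.

## Known limitations

* The scan is single-trait and additive; no epistasis, multi-trait, or
  rare-variant machinery.
* Compression clusters on kinship distance with average linkage only.
* The QTL x QTL chance-expectation construction depends on the bin
  length (median projected-interval length); very heterogeneous interval
  sizes would make the background coarse.
* `anchor_qtl_interval()` needs a supplied chromosome length to close a
  one-sided interval on the right.
* The generator's discrete-block LD makes decay-extent estimates step-like
  at the block length; real decay curves are smooth.
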