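---
title: "Methods: coverage-based PAV genotyping and pan-genome population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based PAV genotyping and pan-genome population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pavpan` genotypes gene presence/absence variation (PAV) from sequencing
coverage and analyses the resulting binary gene-content matrix with standard
population-genetic and association machinery. This vignette records the
models, the conventions, and the design decisions a maintainer would need:
what each stage assumes, which knobs matter, and what the synthetic cohort
used throughout the tests does and does not emulate.

## The presence call

For every gene we take the union of its CDS intervals (each genomic base
counted once, overlapping isoform CDS collapsed) and intersect it with a
per-base depth track. The quantity that drives the call is *breadth*: the
fraction of CDS-union bases covered at depth at least `min_depth` (default
1x). A gene is called **present** in a sample iff breadth >= 0.95, the
threshold being inclusive; otherwise it is absent.

Two readings of "CDS coverage" were possible -- breadth or read-count
normalized mean depth -- and the package commits to breadth: a 0.95 cut-off
is only dimensionally sensible for a fraction in [0, 1]. The mean CDS depth
scaled to depth per million mapped reads (`scale_constant = 1e6`, because no
canonical normalizer exists for this statistic) is still computed and
reported as `norm_depth`, a QC covariate that never enters the call.

Coordinates are fixed once, at the I/O layer: GFF is 1-based inclusive,
depth tracks are BED 0-based half-open, and all internal interval arithmetic
is half-open. Strand is parsed but ignored; coverage is strand-agnostic.
Breadth is kept as the ratio of two integers (`covered_bases / cds_length`)
and compared with `>=` directly, so the 0.95 boundary behaves exactly
(19/20 is present, 9499/10000 is absent).

**Missing calls.** A sample-level QC rule distinguishes *absent* (well-
covered genome, uncovered gene) from *missing* (no evidence either way):
every call of a sample becomes missing when the sample has zero mapped reads
or a genome-wide mean depth below `min_sample_depth` (default 1x). Cell-level
missingness beyond that can be injected by `mask_missing()`; the association
filters are the consumer of this distinction.

## Occupancy bands and saturation

With N classifiable accessions and occupancy k, the frequency f = k/N maps
to: **core** iff f = 1, **softcore** iff 0.97 < f < 1, **shell** iff
0.01 <= f <= 0.97, **cloud** iff 0 < f < 0.01. Two edges needed a decision:

* the softcore band is open at 100% (core takes precedence), otherwise core
  and softcore would double-count genes present in everyone;
* shell is closed at both ends, so that at N = 268 occupancy 259 (96.6%) and
  occupancy 3 (1.12%) are shell while 260 (97.01%) is softcore and 2
  (0.75%) is cloud -- i.e. the integer band edges are 268 / 260-267 /
  3-259 / 1-2.

Occupancy 0 gets the out-of-partition label `absent_everywhere` and is
excluded from the four-way counts. `classify_matrix()` offers two missing
policies: `as_absent` (occupancy over all samples) and
`drop_from_denominator` (per-gene denominator = non-missing calls). The
second is the right choice whenever cell-level missingness exists: with even
2% of cells missing at random, essentially no gene observes all 268
accessions and the strict core band would empty out artifactually.

Saturation curves are drawn by prefix-of-permutation sampling: for each of
`n_permutations` (default 100) random sample orderings, the running
intersection (core) and union (pan) gene counts are recorded at every prefix
size; means and 2.5/97.5 percentile bands are taken across permutations.
Per-permutation, core is non-increasing and pan non-decreasing by
construction -- the tests assert this path by path, and on a 5-sample matrix
they check the permutation mean against the closed-form subset expectation
sum_g C(k_g, n)/C(N, n). Missing calls count as absences inside the
intersection, so the curve should be computed on complete calls.

## The synthetic cohort

The generator produces the statistical structure the analysis assumes, with
full truth tables, and its defaults are the cohort the package is sized for:
268 accessions (91 wild, 177 selection), 1000 genes, 77.23% core.

* **Occupancy spectrum.** Variable genes draw an ancestral presence
  frequency p ~ Beta(0.90, 0.16). This shape was chosen once so that the
  Beta mass in the softcore (> 0.97), shell (0.01-0.97) and cloud (< 0.01)
  bands matches the heavily softcore-weighted spectrum such cohorts show --
  just over half the variable mass above 0.97 and a fraction of a percent
  below 0.01. It is a modelling convenience, not a claim about any real
  occupancy spectrum.
* **Differentiation.** The two populations get independent Balding-Nichols
  frequencies p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F) around each ancestral p,
  with F = `fst_target` (default 0.1). Balding-Nichols was chosen because it
  has a closed-form expected F_ST to recover; the default 0.1 gives a
  genome-wide top-1% per-gene F_ST threshold in the high-0.3s, the order of
  magnitude reported for wild-versus-selection fish cohorts.
* **Selected genes.** A configurable handful of variable genes gets explicit
  (p_wild, p_selection) pairs; the defaults plant one gene falling from
  0.5952 to 0.2621 and two rising from 0.90 to fixation -- the shapes of
  the canonical candidate genes in this setting.
* **Depth.** Presence is inverted back into coverage evidence: the CDS union
  is cut into ~25 bp chunks; present genes draw chunk depths from
  Poisson(`mean_depth`, default 20), with zero chunks promoted to depth 1
  where needed so realized breadth is >= 0.98; absent genes get one random
  contiguous run of depth 1-2 covering a uniform fraction of at most
  `background_breadth` (default 0.3) of the union -- background mismapping.
  Emission is interval-wise, not read-level: read simulation would add
  nothing the coverage rule can see. `total_mapped_reads` is the summed
  depth divided by a 150 bp read equivalent.

What the generator does *not* emulate: linkage between genes (PAVs are
independent, as the per-gene analyses assume), mappability and GC structure
in the background coverage, reference bias, and any correlation between
gene length and presence. Passing the end-to-end recovery tests therefore
shows the pipeline inverts its own generative assumptions at realistic
noise levels -- not that those assumptions hold for any particular real
cohort.

All stages are reproducible from a single integer seed; the generator
saves and restores the caller's RNG state.

## Population genetics on binary calls

**Distance and tree.** d(i, j) is the p-distance over genes non-missing in
both samples. Neighbour joining is delegated to `ape::nj` (Saitou-Nei);
negative branch lengths, possible on non-additive inputs, are clamped to
zero and counted in an attribute. On distances that are exactly additive the
estimated tree reproduces both the split set and the path lengths to 1e-9,
which is how the tests validate it. The methods text of this literature
sometimes pairs a neighbour-joining figure with a maximum-likelihood
pipeline; this package implements NJ only -- an ML tree would wrap an
external tool and add nothing testable here.

**PCA.** Present = 1, absent = 0, missing mean-imputed per gene, centered
per gene and by default scaled by sqrt(p(1-p)) -- the GCTA GRM scaling for
a haploid locus -- then the sample-by-sample covariance is
eigendecomposed. Coordinates are eigenvectors scaled by root eigenvalues,
with each component's sign fixed so its largest-magnitude coordinate is
positive (coordinates are otherwise sign-arbitrary).

**F_ST.** Each accession contributes one haploid allele (present/absent);
haploid encoding is the only one that does not invent heterozygotes for a
binary call. Two per-gene estimators are provided: the Weir-Cockerham
variance-components estimator specialized to haploid counts -- computed
from the one-way ANOVA mean squares as theta = (MSP - MSG)/(MSP +
(n_c - 1) MSG) -- and a Hudson-type 1 - Hw/Hb with the unbiased within
heterozygosity p(1-p)n/(n-1). WC is the default. Estimates are reported
raw: negative values are never clamped, so quantile ranking is unaffected
by clamping policy. Loci monomorphic across both populations, or with
fewer than 2 non-missing calls in either, are flagged undefined.

The empirical scan flags genes at or above the (1 - fraction) quantile
(type-7 linear interpolation -- stated explicitly because "top 1%" is
ambiguous for small marker counts) of defined F_ST values, ties included.

For *parameter recovery* a separate multi-locus summary exists:
`fst_global()` sums the a and b variance components over loci before taking
the ratio, with a delete-one-locus jackknife SE. The mean of per-locus
theta values is a mean of noisy ratios and is biased downward (markedly so
at F = 0.4); the ratio of sums is the consistent combination and is the
quantity the Balding-Nichols recovery tests compare against F.

## Association

Markers pass QC iff minor presence frequency > 0.05 **strictly** and
missing rate < 0.15 **strictly** (a marker exactly at either boundary is
removed). Three models are fit against the binary wild/selection phenotype,
treated as continuous 0/1 -- the convention of the mixed-model GWAS tools
this mirrors:

* **GLM** -- per-marker OLS with intercept and optional PC covariates,
  Wald t-test on the marker coefficient (computed by residualizing marker
  and phenotype against the covariates; exactly `lm`, just vectorized).
* **MLM** -- y = Wa + xb + u + e with u ~ N(0, s2_g K), EMMA-style: K is
  eigendecomposed once, delta = s2_e/s2_g is estimated by REML on the null
  model and fixed across markers (P3D; chosen for determinism and speed --
  the standard approximation), then each marker is tested by GLS in the
  rotated space. The REML surface is profiled on a 41-point grid over
  log delta in [-10, 10] and polished by golden-section search within the
  bracketing interval; a delta pinned at a bound means the data want zero
  (or all) residual genetic variance, which is reported as-is. Kinship is
  VanRaden-type on the presence calls (Z Z' over sum p(1-p), missing
  mean-imputed, eigenvalues floored at 0). With K = I the MLM collapses to
  the GLM exactly, which the tests assert to 1e-8.
* **Fisher** -- two-sided exact test on the 2x2 presence-by-phenotype
  table; the natural baseline when both axes are binary. Effect is the log
  odds ratio, Haldane-Anscombe corrected when a cell is zero.

Two significance flags are always reported: Bonferroni
(p <= alpha/m) and the fixed line -log10(p) >= 5. The fixed-line cut-off in
the source literature is printed as "-log10(p) < 5", which read literally
would make everything significant; it is implemented in the only direction
consistent with a Manhattan-plot threshold. Reporting both flags makes the
ambiguity harmless. Q-Q summaries use expected quantiles
-log10((i - 0.5)/m) and lambda_gc = median observed chi-square over its
null median.

**A calibration note.** With binary markers *and* a binary phenotype the
per-marker t-test statistic is discrete; rejection rates at nominal levels
are calibrated (the tests check 0.035-0.065 at nominal 0.05) but lambda_gc
sits slightly above 1 even under a pure null, purely from the discreteness
of the p-value atoms. Exact uniformity of the p distribution is therefore
asserted on a Gaussian phenotype, where the OLS t-test is exact.

**A confounding note.** When the phenotype is the population label itself
and kinship/PCs are estimated from the same PAV markers, the structure terms
legitimately absorb genome-wide differentiation: an individual marker stays
significant only if its shift exceeds the background. In the bundled
analysis (background F = 0.1, a planted 0.60 -> 0.26 shift), the
uncorrected GLM puts the planted gene far beyond -log10(p) = 5 while the
MLM, with lambda_gc ~ 1, does not -- the expected behaviour, demonstrated
deliberately. The power property itself (median p below the fixed line for
a 0.60 -> 0.26 shift at n = 91/177) is verified in the tests against an
*unstructured* marker background.

## Problem sizes

The test suite and bundled analysis run at sizes chosen to exercise every
code path at the cohort's stated dimensions while staying desk-scale: the
end-to-end recovery uses the full 268 accessions x 1000 genes at 20x
(recovering >= 99% of cells; in practice 100%), oracle sweeps use 1000
random configurations, NJ recovery 200 random 4-8 taxon trees,
Balding-Nichols recovery 2000 loci per F, and the structured-null
mixed-model calibration ~8 replicates of 600 markers x 160 samples.

## Known limitations

* The coverage rule sees only breadth; partially deleted genes above 95%
  breadth, or duplicated genes, are invisible to it.
* Haploid F_ST and the Gaussian 0/1 mixed model are conventions, not
  likelihood-exact treatments of binary traits; a logistic mixed model is
  out of scope.
* The NJ tree carries no support values, and no ML tree is fit.
* The saturation curve's plateau is described, not inferred; changepoint
  estimation is out of scope.
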