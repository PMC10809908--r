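---
title: "Methods: diversity scans, genotype–environment association and RONA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity scans, genotype-environment association and RONA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical
conventions that matter when comparing output against other tools.

## Input model and site filters

`popclim` analyses diploid biallelic SNP dosages (0/1/2 copies of the ALT
allele, `NA` for missing).  Ingestion applies the hard site filters that
population-resequencing studies conventionally run through VCFtools, in
VCFtools semantics: biallelic SNPs only; site QUAL ≥ 30; mean genotype
depth ≥ 3 (both skipped with a warning when the VCF lacks the fields,
since they are often applied upstream); call rate ≥ `max_missing` (note
that VCFtools' `--max-missing 0.2` keeps sites with at least 20% of
genotypes called — a permissive filter, reproduced literally and exposed
as a parameter); and minor-allele frequency ≥ 0.05 computed on called
alleles over the full sample set.  Half-calls (`./1`) carry incomplete
information and are treated as missing.  MAF is computed once at
ingestion and *not* recomputed per analysis subset, matching the
single-filtered-SNP-set design of such studies; `recompute_maf_on_subset()`
is available when per-subset filtering is wanted.  Internal coordinates
are 1-based throughout (VCF/GFF convention); conversion to 0-based
half-open intervals happens only in `write_bed()`.

## Diversity and differentiation

**π.** Per-site pairwise diversity is the fraction of differing haploid
allele pairs among the `m` called alleles, `2p̂q̂·m/(m−1)`.  Windowed π
divides the site sum by the *physical window length* (100 kb by default),
the VCFtools `--window-pi` convention; dividing by the number of analyzed
sites instead is available behind `denominator = "sites"`.  The two differ
by the SNP density, which matters when comparing absolute π across
datasets.

**Weir–Cockerham F_ST.** The 1984 variance-components estimator for
diploid genotype data, computed from observed genotype counts (including
observed heterozygote frequencies — no HWE shortcut).  Populations with
fewer than two called individuals at a site are excluded at that site.
Site estimates are `a/(a+b+c)`, undefined at sites monomorphic across all
groups, with negative estimates retained.  Windowed values use the
"weighted" ratio-of-sums `Σa/Σ(a+b+c)` (VCFtools' weighted Fst); the mean
of per-site ratios is exported behind `estimator = "mean"`.  Undefined
windows are emitted with `NA`, never dropped, so tracks on the same grid
stay alignable.

**Tajima's D.** The standard 1989 normalization.  Because the called
allele count varies across sites in real data, the window's normalizing
constants use the *modal* per-site called-allele count, while each site's
pairwise term uses its own count — a documented approximation relative to
tools that assume a fixed sample size per window.  Windows with no
segregating sites, or modal count below 4, are undefined.

**LD.** r² is the squared Pearson correlation of dosage vectors over
jointly called samples (composite LD on unphased data — the same choice
as PopLDdecay's genotype mode), binned by pair distance up to 500 kb.
`decay_distance_at()` reports where a monotone (isotonic) smoothing of the
curve first drops below a threshold; the monotone fit guards against
noisy bins reversing the decay.

## Structure, IBD and IBE

PCA follows the GCTA/Patterson convention: per-locus mean imputation,
centering by `2p̂`, scaling by `sqrt(2p̂(1−p̂))`, eigen-decomposition of the
sample kernel, with a deterministic sign convention (the largest-|loading|
locus entry is positive).  Geographic distances are haversine great-circle
distances (Earth radius 6371.0088 km) between population centroids.
Environmental distances are Euclidean on per-EV z-scores, making them
invariant to each variable's raw units.

The Mantel test correlates upper-triangle entries and permutes population
labels jointly over rows and columns; the one-sided p-value is
`(1+#[r* ≥ r])/(n_perm+1)` with 999 permutations by default, as in vegan.
Mantel tests run at the *population* level (the distance matrices are
population-labeled).  To make the result independent of argument order
under a fixed seed, permutations are applied to a canonically chosen
matrix (the one with the smaller entry sum); since the correlation is
symmetric this is a pure implementation convention.  The
isolation-by-environment contrast compares two Mantel tests on
F_ST/(1−F_ST) matrices: one from the key EALs ("adaptive variants") and
one from LD-pruned non-outlier loci (greedy pruning at r² > 0.2 within
50 kb — the pruning rule is a package choice, since only the contrast
itself is conventional).  Negative pairwise F_ST is floored at zero
before the linearizing transform so the matrix stays non-negative.

## Selective sweeps

The scan contrasts each group against the pooled remainder (pairwise
contrasts are available).  The θπ ratio is oriented `π_reference/π_focal`
so that reduced focal diversity lands in the *top* tail, consistent with
selecting the top 5% of ratios; the orientation is a parameter.  Windows
where both diversities are zero are undefined; `π_focal = 0` with
`π_reference > 0` gives `Inf`, which always passes the ratio cut.
Thresholds are type-7 empirical quantiles with strictly-greater-than
selection; with `q ≥ 1` every defined window is selected.  Selected
sliding windows (100 kb, 1-kb steps) are merged into regions, and genes
overlap a region by ≥ 1 bp of 1-based inclusive span.

## Genotype–environment association

The latent-factor association model is the standard two-stage
approximation of an LFMM: structure is estimated once genome-wide as the
top-K genotype PCs, then each (locus, EV) pair is fit by least squares of
dosage on `[1, EV, U]` with population-level EVs broadcast to member
samples.  K defaults to the number of groups minus one; a scree-gap
helper (`suggest_k()`) is provided.  The EV is standardized internally
for numerical conditioning; reported effects are on the raw EV scale and
z-scores are invariant to affine EV rescaling.

Calibration: the genomic inflation factor is `λ = median(z²)/0.4549`
(median of χ²₁).  Two finite-sample refinements apply, both chosen
because the cohort sizes this package targets (~100–400 samples) are an
order of magnitude below the asymptotic regime of the usual convention:

* p-values use the exact Student-t null with the model's residual degrees
  of freedom rather than the normal/χ² tail.  z *is* a t statistic; at
  n = 120 the χ² tail is anti-conservative by ~2.5× at |z| ≈ 4.7, which
  measurably inflates the far tail where the key-EAL rule operates.  At
  n ≈ 440 the two references agree to well under 10%.
* As in classical genomic control, λ rescales z² only when λ > 1:
  apparent deflation (which arises from latent-factor overfitting) is
  never converted into extra significance.

The decision thresholds themselves are the conventional ones: key EALs
satisfy |z| ≥ 4 and calibrated p ≤ 1e−5, with Benjamini–Hochberg
q-values per EV and no cross-EV multiplicity correction (results are
reported per EV).  EVs are first pruned greedily at |Pearson r| > 0.8 in
priority order.  The scan runs genome-wide by default; an empirical
F_ST-outlier prescreen (`fst_outlier_prescreen()`, top-quantile of
per-site multi-population F̂) is provided for workflows that restrict the
scan to divergence outliers, as a lightweight empirical stand-in for a
Bayesian outlier scan.

A known limitation, visible in the package's own null simulations: for
low-frequency alleles private to one geographic group, the pooled OLS
residual variance understates the variance of the group that carries the
allele, and the t statistic can exceed the key threshold without any
environmental effect.  This heteroscedasticity artifact is intrinsic to
least-squares dosage regression and is the main source of the small
residual false-positive rate (≈ 1e−3 of neutral loci at the default
settings).

## Partial RDA

`partial_rda_fit()` implements the textbook algorithm: residualize the
(mean-imputed, centered) dosage response and the z-scored EV matrix on
`[1, lon, lat]`, fit the multivariate regression, and decompose the
fitted values by SVD.  Variance bookkeeping (conditioned + constrained +
residual = total) matches vegan's `rda()` exactly, as the test suite
verifies.  SNP loadings follow the vegan species-score convention
(covariance-type, `t(Y⊥)u`); per-locus correlations with each axis are
returned alongside.  EVs annihilated by the conditioning variables (an EV
that is a linear function of longitude/latitude) are dropped with a
warning rather than fit as floating-point noise; if all EVs are
annihilated the constrained variance is reported as exactly zero.

Outliers are loci whose loadings fall outside mean ± 1.96 SD on any of
axes 1–3 ("95% confidence interval" read as two-sided normal tails; the
± 3 SD convention common in landscape genomics is available via
`cutoff_sd`), each attributed to its max-|loading| axis and that axis's
strongest-|biplot| EV.  Significance uses the pseudo-F with a null built
by permuting rows of the residualized response; permuted responses are
re-residualized on the conditioning matrix before projection — omitting
that step leaves conditioning variance in the permuted residual and makes
the test anti-conservative, a defect the permutation-calibration test
would catch.  The response defaults to the key-EAL dosage matrix at the
individual level (populations color samples, EVs are broadcast), and the
pipeline reports the intersection of RDA outliers with the LFMM key set
alongside both parent sets.

## RONA

For each EV with future projections, loci are the LFMM records at
calibrated p < 1e−3 (the calibrated rather than raw p, for consistency
with the scan stage).  Populations with fewer than 7 individuals are
dropped ("more than six" retained).  Per locus, ordinary regression of
population allele frequency on the current EV gives `(a, b, R²)`; the
required future frequency is `clamp(a + b·EV_future, 0, 1)` and the
per-locus distance is its absolute difference from the population's
*observed* current frequency (the regression-fitted baseline is available
via `current = "fitted"`; observed is the default since the projection
should be anchored at where the population actually is).  RONA is the
R²-weighted mean distance — the weighting of the original formulation —
with an unweighted option, and an unclamped diagnostic column.  Means and
standard errors (`sd/√m`) are aggregated across climate models per
population × EV × scenario, with the SSP585 − SSP126 contrast of means.
With noiseless linear clines and a uniform shift Δe, RONA equals
`mean(|b|)·Δe` exactly; `rona_closed_form_check()` exercises that
identity through the production code path.

## The synthetic cohort

`sim_config()` defines the study conditions the test suite and the
acceptance script run under.  The default cohort is 4 geographic groups ×
3 populations × 10 individuals (120 samples — a ~3.6× scaled-down
analogue of a ~440-sample range-wide collection, sized so that a full
pipeline run takes about half a minute), with ~20,000 filter-passing SNPs
on two 5-Mb chromosomes.

* **Allele frequencies** follow the hierarchical Balding–Nichols model:
  group frequencies are Beta draws around a shared ancestral frequency at
  `F = 0.25` (pairwise group F_ST lands near 0.25, inside the 0.1–0.4
  band typical of strongly structured tree populations), then population
  frequencies drift within groups at `F = 0.01` (pairwise within-region
  F_ST ≈ 0.02).  Ancestral frequencies default to a `1/(p(1−p))` density
  truncated to [0.06, 0.94] — the spectrum that survives a MAF ≥ 0.05
  filter; a standard-neutral `1/p` option exists for calibration fixtures
  that must not be MAF-truncated.  A consequence of the filtered spectrum
  worth knowing: genome-wide Tajima's D is strongly positive (≈ +3 in the
  default cohort), as rare variants are absent by construction.
* **Geography and environment.**  Group centers are placed as overlapping
  montane provinces (latitude 31–38°, longitude 100–111°, altitude bases
  1200–2800 m), with populations scattered ±3° and ±600 m within regions
  and nine EVs (temperature, precipitation, radiation, vapour pressure,
  altitude) generated as linear spatial trends plus noise.  The within-
  region spread is deliberate: when environmental variance collapses onto
  the group axes, any structure-corrected method is confounded by
  construction and planted clines become undetectable — early versions of
  the generator with ±1.5° spreads demonstrated exactly that.
* **Adaptive loci** have population frequencies
  `logistic(a + b·z(EV))` with |b| ∈ [4, 6] — steep clines spanning most
  of the frequency range (and in particular more than 0.4 of it), the
  regime in which key-EAL calling is intended to operate.  They are
  simulated unlinked from their neighbours so that recovery metrics are
  unambiguous.
* **LD** is produced by a Gaussian AR(1) copula along each chromosome:
  latent haplotype correlation decays as `exp(−d/10 kb)` while marginal
  allele frequencies are preserved exactly.  This gives monotone r² decay
  on the right length scale but none of the block structure, hotspots, or
  demography-driven long-range LD of real genomes.
* **Sweeps** collapse the focal group's haplotype pool inside a planted
  span: frequencies are pushed toward fixation by the diversity-reduction
  factor (default 0.15) with divergence boosted 3×, reducing focal π and
  raising focal-vs-rest F_ST jointly.
* **Filter-failing records** (indels, multi-allelic sites, low MAF, low
  call rate, low QUAL, low depth) are planted in the emitted VCF with
  their reasons recorded, so ingestion can be scored site-by-site; loci
  whose realized MAF drifts below the floor are reclassified as failing.
* **Futures** are uniform additive EV shifts per scenario × model (three
  CMIP6-style models, SSP126 vs SSP585) — no spatial raster variation,
  which keeps the closed-form RONA property exact.

What passing tests on this cohort do *not* show: robustness to coalescent
LD structure, unbalanced sampling, genotyping error correlated with depth,
EV measurement error, or polygenic (many-small-effect) adaptation — the
generator plants strong monogenic clines only.

## Calibration fixtures

Two dedicated fixtures back the calibration tests.  The association-scan
null uses the default cohort geometry with within-region drift reduced to
`F = 0.001` and no planted signal: the genetic structure is then genuinely
four-group (matching K = 3 latent factors) while the EVs keep twelve
distinct population values.  The alternative realization — one population
per group — is degenerate, because population-level EVs then take only
four values and are exactly confounded with the latent factors.  The
Tajima's-D neutrality fixture is a single panmictic population with the
standard-neutral spectrum and no MAF floor.

## Determinism and numerical conventions

Every stochastic component takes an explicit seed; the pipeline derives a
per-stage substream from the master seed (fixed offsets, so adding a
stage never perturbs earlier streams), and reruns with the same seed are
byte-identical, which the test suite asserts file-by-file.  Quantiles are
type 7; thresholds select strictly above; PCA and RDA axes carry the
largest-|loading|-positive sign convention; undefined values propagate as
`NA` rather than being silently dropped.  Problem sizes in the test suite
(3,000–20,000 loci, 120 samples, 100–500 permutation replicates) were
chosen as the smallest at which the distributional checks have useful
power.
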