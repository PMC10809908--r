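# popclim

Landscape genomics of local adaptation in structured plant populations:
from a filtered SNP matrix to selective-sweep scans, genotype–environment
association, and projected climate-maladaptation risk.

## What it is for

Range-wide resequencing studies of long-lived plants ask three linked
questions: where in the genome has selection acted (selective sweeps),
which variants track environmental gradients today (environment-association
loci, EALs), and how far current populations will sit from their adaptive
optima under future climates (risk of non-adaptedness, RONA). `popclim`
implements that full analysis chain for diploid biallelic SNP data from
hierarchically structured populations, together with a seeded synthetic-data
generator whose recorded ground truth makes every stage testable.

The pipeline stages and their core statistics:

* **Ingestion** — VCF site filters in VCFtools semantics (biallelic SNPs,
  QUAL, mean depth, call rate, MAF ≥ 0.05 on called alleles); GFF3 gene
  models; sample and environment tables with `EV:SCENARIO:MODEL` future
  columns.
* **Diversity / differentiation** — windowed nucleotide diversity
  π (per-bp, 100-kb windows), Weir–Cockerham (1984) F_ST from variance
  components *a*, *b*, *c* with the weighted windowed form
  Σa / Σ(a+b+c), Tajima's D, and LD decay r²(d) from dosage correlations.
* **Structure** — GCTA-convention genotype PCA; Mantel tests of
  F_ST/(1−F_ST) against great-circle distance (IBD) and against
  z-scored environmental distance (IBE), 999 permutations.
* **Sweeps** — joint top-5% windows of focal-vs-rest F_ST and the
  θπ ratio π_ref/π_focal, merged into regions and annotated with
  overlapping genes.
* **GEA** — correlation pruning of EVs (|r| > 0.8), K latent factors from
  genotype PCA, per-locus least squares of dosage on [1, EV, U],
  genomic-inflation calibration, and the key-EAL rule |z| ≥ 4 &
  p ≤ 1e−5; partial RDA of candidate dosages on EVs conditioned on
  longitude/latitude, with 95%-tail loadings on axes 1–3 as outliers and
  permutation significance.
* **RONA** — per-locus regressions of population allele frequency on the
  current EV; RONA is the R²-weighted mean |required − observed|
  frequency change under each scenario × climate model, aggregated to
  means ± SE across models.

## Worked example

Simulate the default cohort (4 geographic groups × 3 populations × 10
individuals, ~17k filtered SNPs on two 5-Mb chromosomes, planted adaptive
clines and sweeps), then run the association scan:

```r
library(popclim)

cfg    <- sim_config(seed = 7)
bundle <- simulate_dataset(cfg)
bundle$genotypes
#> genotype_matrix: 120 samples x 17300 loci on 2 chromosome(s)
#>   missingness: 2.98%

evs <- prune_evs(bundle$env)          # |r| > 0.8 pruning keeps 6 of 9 EVs
U   <- fit_latent_factors(bundle$genotypes, K = 3)
eals <- lfmm_scan(bundle$genotypes, bundle$env, bundle$samples, U,
                  evs = evs)
round(attr(eals, "lambda"), 2)
#>   bio1   bio2   bio3  bio13  bio19 srad12
#>   1.05   1.12   1.17   1.10   1.09   1.14

key <- unique(eals$id[eals$key])
length(key)
#> [1] 64
```

Of the 60 planted clinal loci, 45 (75%) are flagged as key EALs in this
single run; the genomic inflation factors near 1.1 reflect the residual
within-region population structure that three latent factors do not absorb.
`make_demo(outdir, seed)` runs the whole pipeline on such a fixture and
writes a `scorecard.json` scoring sweep recall, EAL precision/recall and
the closed-form RONA error against the generator's ground truth.

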