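# hzgenomics

Tools for dissecting the genomic architecture of divergence and
introgression in hybrid zones between differentiated taxa, built around
the analysis needs of avian (ZW) systems: a pair of parental populations,
a transect of admixed individuals, a large sex-chromosome inversion, and
ordinal plumage phenotypes.

## What it computes

- **Divergence scans** — per-site and 50-kb-windowed Weir–Cockerham
  F<sub>ST</sub> (variance components *a/(a+b+c)*, haploid-aware),
  nucleotide diversity and Tajima's D, and a dual-comparison
  elevated-window rule: a window is an outlier only if its mean
  F<sub>ST</sub> exceeds the 99th percentile **and** contains a fixed SNP
  (per-site F<sub>ST</sub> = 1) **and** is also elevated in the
  backcrossed comparison.
- **Inversion detection** — local PCA in 100-SNP windows, window
  comparison by Frobenius distance between rank-2 covariance
  reconstructions, classical MDS with 99th-percentile outlier flagging,
  contiguous-cluster span estimation, three-cluster karyotyping on PC1
  with a heterozygosity validation, and Fisher/Benjamini–Hochberg
  gene-set enrichment.
- **Population structure** — genotype PCA (Patterson scaling), K = 2
  admixture by binomial-likelihood EM (whole-genome and in 100,000-SNP
  chunks), hybrid classification from hybrid index + interspecific
  heterozygosity, and fixed-SNP genotype-class matrices polarized against
  a reference individual.
- **Plumage association** — EMMA-style linear mixed model GWAS with a
  genomic relationship matrix (Wald tests, −log₁₀ p ≥ 7), outlier
  collation across traits with ±40-kb gene mapping, one-SNP-per-Mb
  thinning by F<sub>ST</sub>, an additive-versus-epistatic regression
  battery over cross-chromosome SNP pairs, and the melanin-PC1 versus
  total-plumage-score regression.
- **AIM panels** — four marker categories: fixed differences, 55–65th
  percentile background markers ≥50 kb from exons and ≥50 kb apart,
  melanin GWAS candidates, and inversion-linked SNPs.
- **Geographic clines** — sigmoid clines
  p(x) = pmin + (pmax−pmin)·(1 + tanh(2(x−c)/w))/2 with none/mirror/both
  exponential tail models, fit by adaptive Metropolis–Hastings MCMC on
  binomial locality counts; two-log-likelihood profile support intervals,
  AICc tail-model selection, and coincidence/concordance tests between
  marker classes.
- **A synthetic hybrid zone** — Balding–Nichols parental frequencies at a
  target F<sub>ST</sub>, planted fixed-difference windows, a
  recombination-suppressing Z inversion, explicit gamete simulation for
  parental/F1/backcross/F2 classes, hemizygous females, clinal transects,
  and liability-based 0–4 plumage scores, all with a truth record for
  parameter-recovery testing.

## A worked example

```r
library(hzgenomics)

cfg <- sim_config(seed = 3)              # two autosomes + Z, 60 birds
mod <- build_parental_model(cfg)
ds  <- simulate_cohort(mod, cfg, "cohort")

pa <- ds$samples$id[ds$samples$class == "PA"]
pb <- ds$samples$id[ds$samples$class == "PB"]
wc_fst(ds$geno, pa, pb)$weighted
#> [1] 0.2010301
```

The genome-wide Weir–Cockerham estimate (0.201) reflects the 0.19
baseline plus the more divergent planted windows and Z inversion.
Scanning for the inversion:

```r
map  <- local_pca_windows(ds$geno, window_snps = 100)
scan <- mds_outlier_scan(map, axis = "auto")
estimate_inversion_span(scan, merge_gap = 5e6)
#>   chrom   start      end length_bp n_clusters
#> 1     Z 9987392 39058791  29071399          2
```

which recovers the planted 10–40 Mb inversion (29.1 of 30 Mb, two
merged MDS-outlier clusters). Karyotyping it:

```r
ky <- karyotype_individuals(ds$geno, cfg$inversion, anchor_a = pa)
table(ky$calls$karyotype, ds$samples$true_karyotype)
#>       AA AB BB
#>   AA  30  0  0
#>   AB   0  9  0
#>   BB   0  0 21
ky$female_ab          # no female heterokaryotypes on Z
#> [1] 0
```

Cline fitting on a simulated transect (true melanin cline: center 175 km,
width 275 km):

```r
tr <- simulate_cohort(build_parental_model(cfg), cfg, "transect")
lf <- locality_frequencies(tr)
fit <- fit_cline(lf[lf$marker_class == "melanin", ], tail = "none", seed = 1)
round(fit$map_par, 1)
#> center  width
#>  165.4  279.8
round(fit$support["center", ], 1)
#>    lo    hi
#> 158.6 172.3
```

The width is recovered within 2%; this particular transect draw places
the center estimate ~10 km west of truth — a reminder that 12
localities of 15 birds leave real sampling noise in the center.

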