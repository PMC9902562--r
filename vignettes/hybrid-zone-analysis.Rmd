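---
title: "Dissecting hybrid-zone genomic architecture with hzgenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hybrid-zone genomic architecture with hzgenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

When two differentiated taxa meet and hybridize along a geographic
transect, the genome becomes a mosaic: most regions introgress freely,
while regions harboring barrier loci stay differentiated. `hzgenomics`
implements a connected set of analyses for dissecting that architecture in
a ZW-sex-determined avian system:

1. windowed divergence scans with a dual-comparison elevated-window rule;
2. local-PCA/MDS detection and karyotyping of large chromosomal
   inversions;
3. admixture estimation (whole-genome and windowed) and hybrid
   classification;
4. mixed-model GWAS of ordinal plumage traits with an epistasis battery;
5. ancestry-informative marker (AIM) panel design;
6. geographic cline fitting with tail models and concordance tests.

Every stage is verifiable at desk scale against a synthetic hybrid-zone
generator that carries a full truth record.

# The synthetic hybrid zone

`sim_config()` + `build_parental_model()` + `simulate_cohort()` generate
genotypes with the statistical structure the analyses assume.

**Parental frequencies.** Per-site allele frequencies for the two parental
populations are drawn from a Balding–Nichols model: an ancestral frequency
$p \sim \mathrm{Unif}(0.05, 0.95)$ and population frequencies
$p_{A}, p_{B} \sim \mathrm{Beta}\!\left(p\tfrac{1-F}{F},
(1-p)\tfrac{1-F}{F}\right)$, where $F$ is the target genome-wide
$F_{ST}$ (default 0.19, the differentiation scale typical of mid-stage
avian divergence). A one-time simulation check at 50,000 sites showed the
realized Weir–Cockerham ratio-of-sums estimate between two sampled
populations tracks the nominal $F$ within a few percent across targets
from 0.05 to 0.4, so no calibration factor is applied. Planted
high-divergence windows set $|p_A - p_B| = 1$ (fixed differences) over a
50-kb interval.

**The inversion.** A Z-linked interval (default 10–40 Mb on a 75-Mb Z)
carries opposite, fixed orientations in the two parental populations.
Gametes are simulated explicitly: one crossover per chromosome per meiosis
at a uniform position (rate configurable), and a crossover proposed inside
the inversion interval of a karyotype-heterozygous parent is suppressed —
so recombinant haplotypes inside the inversion are exactly absent, the
property that makes the three-cluster local-PCA signature and elevated
heterokaryotype heterozygosity emerge rather than being painted on.
SNP density inside the inversion follows the Z default; the inversion's
allele-frequency divergence (default 0.5) exceeds the autosomal baseline,
reflecting the elevated Z differentiation characteristic of such systems.

**Sex.** Sex is assigned 50:50; females are hemizygous on Z, encoded as
diploid dosage in {0, 2} with a haploid flag so one matrix type serves all
chromosomes (this matches how haploid GT calls appear in VCFs). Female Z
copies descend from the father, and only males can be inversion
heterokaryotypes.

**Genotypic classes.** Cohort mode draws parental (PA/PB), F1, backcross
(BCA/BCB) and F2 individuals through explicit gametes, mirroring the five
genotypic classes sampled in hybrid-zone studies. F2 individuals are
formed from two F1 male gametes — an abstraction that slightly simplifies
Z transmission but preserves autosomal expectations. Transect mode instead
draws each haplotype from the true cline frequency of its marker class at
the sample's locality; inversion-interval alleles are drawn conditional on
the haplotype's orientation, itself clinal.

**True clines.** Default class clines use center/width values of
175/275 km (melanin), 214/362 km (fixed), and 177/244 km
(inversion-linked) over a 0–550 km transect with 12 localities — the
scale of a riverine hybrid-zone transect.

**Plumage traits.** Nine ordinal traits are generated from a liability
model: additive effects times dosage plus epistatic effects times the
centered product coding $(g_1-1)(g_2-1)$, plus Gaussian noise (default SD
0.5). The liability is standardized and cut at fixed points
$(-1.5, -0.5, 0.5, 1.5)$ shared across traits, giving integer scores 0–4
(total 0–36). The cut-points are a convention: the field's visual scoring
rubric is not generative, so any monotone mapping is equally defensible;
fixed shared cut-points make tests deterministic.

**What the generator does not emulate.** Linked selection, recombination
hotspots, multi-generation backcross pedigrees, genotyping error beyond
uniform missingness, and reference bias. Passing recovery tests on these
simulations therefore demonstrates the estimators' correctness and power
under idealized polymorphism structure, not robustness to every real-data
pathology.

# Divergence statistics and the elevated-window rule

`wc_fst()` implements the two-population Weir–Cockerham variance-components
estimator with haploid-aware allele counting (a hemizygous call contributes
one allele and cannot be heterozygous). Genome-wide summaries use the
ratio-of-sums form $\sum a / \sum (a+b+c)$. A site fixed for opposite
alleles with no heterozygosity information returns exactly 1; the boundary
is set explicitly because the variance-component cancellation is exact
only in real arithmetic, and the fixed-SNP flag downstream requires
exactness. Negative per-site estimates are retained in window means —
truncation would bias the percentile threshold.

`windowed_stats()` works on a fixed 50-kb grid; windows with fewer than 10
SNPs are flagged `dropped` and excluded from percentile pools. The window
mean is the unweighted average of defined per-site values (the behavior of
the standard windowed-FST tooling); the weighted ratio-of-sums is stored
alongside for comparison. Nucleotide diversity is the average pairwise
difference per bp, and Tajima's D uses the standard
$a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ constants with $n$ set to the
mean called allele count; at $n = 2$ both the numerator and the variance
constants vanish and D is reported as exactly 0.

`detect_elevated_windows()` calls a window elevated only when (i) it is
autosomal and not dropped, (ii) its allopatric mean $F_{ST}$ exceeds the
99th percentile of windowed means, (iii) it contains at least one fixed
SNP, and (iv) its backcross-comparison mean also exceeds that comparison's
own 99th percentile. The rationale is that allopatric drift-driven peaks
erode under hybrid-zone gene flow, so only windows elevated in both
comparisons plausibly mark reproductive-isolation loci. Z windows are
summarized descriptively but excluded from the call set, because Z-wide
elevation would otherwise dominate an autosomal percentile rule; an
aggregate joint-percentile summary over all chromosomes is also emitted.

For power, the recovery experiment allocates its 60 samples to the four
classes the scan consumes (PA/PB 20%, backcrosses 30% each): single-meiosis
backcross gametes inherit large blocks, so backcross-comparison window
frequencies are noisy and benefit from more meioses per group.

# Inversion detection and karyotyping

`local_pca_windows()` computes, in non-overlapping 100-SNP windows, the
centered sample covariance normalized to unit trace and stores its top-2
eigenpairs. Windows are compared by the Frobenius distance between their
rank-2 covariance reconstructions — a quantity invariant to eigenvector
sign flips and to rotations within degenerate eigenspaces, which resolves
the inherent ambiguity in "distances between principal components"
(PC coordinates themselves are only defined up to sign and rotation). A
Procrustes-style coordinate distance was considered and rejected as the
default because it needs an arbitrary alignment choice per pair.

`mds_outlier_scan()` embeds the distances by classical MDS and flags
windows whose |coordinate| on the scanned axis exceeds the 99th
percentile. Two practical points:

- **Axis choice.** Classical MDS orders axes by eigenvalue, so a localized
  anomaly (an inversion on one chromosome) is not guaranteed to load on
  axis 1 — in simulations it lands on axis 2 in a minority of runs. The
  default scans axis 1; `axis = "auto"` scans the axis with the heaviest
  outlier tail (largest kurtosis), which is what the inversion-detection
  pipeline uses.
- **Cluster growth.** A hard percentile cut flags ~1% of windows by
  construction and therefore fragments genuinely contiguous anomalous
  regions. Clusters are maximal runs of flagged windows with a 2-window
  gap tolerance, and each cluster's span then grows through adjacent
  windows above a softer hysteresis threshold (half the hard threshold by
  default) — standard two-threshold detection. Cluster `n_windows` always
  counts only hard-threshold windows, so null-calibration properties
  (~1% flagged; no long spurious runs) are unaffected.

`estimate_inversion_span()` merges same-chromosome clusters within a
configurable gap and reports span and length as the coordinate difference
`end - start`. `karyotype_individuals()` runs a PCA on region SNPs,
k-means (k = 3, deterministic quantile-initialized centers) on PC1 — the
inversion-dosage axis — labels the middle cluster AB, attaches observed
heterozygosity, and reports a one-sided Mann–Whitney test of the
heterokaryotype-heterozygosity prediction plus the count of females called
AB (structurally impossible for a Z inversion; any nonzero count flags a
problem). `enrichment_test()` is a plain two-sided Fisher exact test per
gene set with Benjamini–Hochberg correction over sets.

# Population structure and admixture

`genotype_pca()` mean-imputes, drops monomorphic sites, and by default
applies Patterson scaling $1/\sqrt{p(1-p)}$. `admixture_fit()` fits the
classic K-component binomial admixture likelihood
$\prod_{ij} \binom{2}{g_{ij}} \pi_{ij}^{g_{ij}} (1-\pi_{ij})^{2-g_{ij}}$,
$\pi = QF$, by plain EM — the same likelihood the standard admixture
tools optimize, chosen over sequential quadratic programming for
simplicity at desk scale. The log-likelihood is checked every iteration
and a decrease beyond 1e-8 aborts the run; convergence is a gain below
1e-6. Label switching is resolved by anchoring component 1 to supplied
parental-A samples. Q values of parental individuals approach 1 exactly
only when diagnostic (fixed-frequency) sites inform the fit; on arbitrary
polymorphic panels a parental sample can sit a few percent off purity at
finite marker counts. `windowed_admixture()` applies the same fit in
coordinate-ordered chunks with anchor-aligned labels. `classify_hybrids()`
computes hybrid index and interspecific heterozygosity over fixed AIMs;
the class thresholds (parental HI ≤ 0.05 or ≥ 0.95 with het ≤ 0.1; F1
at HI 0.4–0.6 with het ≥ 0.85; backcross bands otherwise) are documented
conventions, configurable, since the primary literature delegates them to
prior work.

# Plumage GWAS and the epistasis battery

`kinship_grm()` is the centered, frequency-standardized genomic
relationship matrix. `lmm_gwas()` is an EMMA-style fit: eigendecompose K
once per trait, estimate the variance ratio $\delta$ on the rotated null
model by 1-D ML optimization, then hold it fixed for per-SNP generalized
least squares (the EMMAX approximation). The Wald statistic
$(\hat\beta/\mathrm{se})^2$ is referred to $F(1, n-2)$ with the per-SNP
weighted residual variance on $n-2$ degrees of freedom, so with
K = identity the test reduces *exactly* to the ordinary least-squares
Wald test — a reduction the test suite asserts at 1e-6. The significance
threshold is $-\log_{10} p \ge 7$, treated as a fixed convention. Ordinal
scores are analyzed as numeric, as the field's mixed-model GWAS tools do.
Missing genotypes are imputed by per-site allele frequency — a deliberate
simplification relative to haplotype-based imputation, adequate at the
simulated missingness levels.

`thin_candidates()` keeps the highest-$F_{ST}$ SNP per megabase
(ties to the lower coordinate), and `epistasis_battery()` fits, per trait
and cross-chromosome SNP pair, additive (`score ~ g1 + g2`) and
interactive (`score ~ g1 * g2`) linear models with 3-level factor coding;
the interaction is tested by the nested-model F-test and additive terms by
marginal F-tests, with genotype classes under 3 samples collapsed into the
nearest class and flagged. Summary counts are reported at α = 0.05 with
an additional strong tier at 5e-4, both over the full enumeration and
excluding single-SNP models (the two conventions found in practice).

# Geographic clines

`cline_frequency()` implements the sigmoid
$p(x) = p_{min} + (p_{max}-p_{min}) \cdot \tfrac{1}{2}(1 + \tanh(2(x-c)/w))$
with optional exponential tails: beyond a distance $\delta$ from the
center on either side, the unit cline continues as an exponential in $x$
whose slope at the junction is $\tau$ times the central cline's slope
there, with continuity enforced by construction ($\tau \in [0,1]$; mirror
mode copies the left tail to the right). This is a fully specified
contract reproducing the qualitative behavior of the classical
tail-augmented cline families; the exact parameterization of legacy cline
software is not reproduced, so validation rests on self-consistent
parameter recovery rather than numeric identity with that software.

`fit_cline()` maximizes the binomial likelihood of per-locality allele
counts by per-parameter Gaussian random-walk Metropolis–Hastings, with
proposal scales adapted during burn-in to a 20–40% acceptance target and
uniform priors (center within the observed range ± one range-width; width
up to 3× the range; δ within the range; τ in [0,1]). `fix_ends` pins the
end frequencies to 0 and 1 — the natural reading of fixing the cline's
mean/variance to the parental states. The MAP is polished by local
optimization from the best draw. Support intervals follow the
two-log-likelihood rule computed from the *profile* likelihood by
constrained optimization (the faster posterior-draw range is available via
`support = "samples"` but is systematically narrower). By χ² asymptotics a
2-unit profile drop gives ≈95% coverage per parameter; joint coverage of
center and width together is expected near 86%, so coverage claims are
made for the center. Posterior quantile intervals are also emitted.

`select_tail_model()` compares tail modes by AICc (ties to fewer
parameters); `concordance_report()` flags pairwise coincidence (center
interval overlap) and concordance (width interval overlap), reports
center offsets against a designated control class, and summarizes each
fitted cline's longer-tail direction as a sign.

# Problem sizes and determinism

The recovery experiments run at deliberately modest sizes chosen as
realistic desk-scale analogues: a 100k-SNP, 60-sample genome for the
divergence scan; a 75-Mb Z with a 30-Mb inversion at ~2,800 Z SNPs for
the inversion scan (so the ~1%-of-windows outlier budget of the percentile
rule can tile the planted interval); 10k sites for admixture recovery;
5k SNPs × 150 samples for GWAS calibration; 12 localities × 30–60 alleles
for cline experiments, with 20 replicates for coverage and model-selection
rates. All randomness flows from explicit seeds; identical configuration
and seed reproduce outputs byte-for-byte.

# Known limitations

- The one-crossover recombination model gives large ancestry blocks;
  window-level statistics over backcross groups are correspondingly noisy
  at small sample sizes.
- The admixture EM, while monotone and correct, converges slowly near the
  optimum compared to quasi-Newton implementations; at 10k sites × 60
  samples a fit takes tens of seconds.
- Ordinal traits are analyzed as numeric in the LMM; an ordinal-logit
  sensitivity analysis is a natural extension but is not implemented.
- Cline tails are exponential with a slope-ratio parameterization; fits to
  data generated under other tail families are approximations.
- The amplicon workflow (primer design, wet-lab protocol) is out of scope;
  the package starts from genotype calls.
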