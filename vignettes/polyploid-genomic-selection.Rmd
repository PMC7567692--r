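---
title: "Dosage-aware genomic selection in autopolyploids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-aware genomic selection in autopolyploids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyGS)
```

# The problem

In autopolyploid crops (tetraploid potato, hexaploid sweetpotato) a
biallelic locus carries 0..p copies of the alternative allele. Meiosis is
polysomic: all p homologs can pair, so gamete composition follows
combinatorial rather than disomic rules, heterozygotes come in p − 1
distinguishable dosage classes, and sequencing-based genotyping must
separate those classes from read counts — which it can only do reliably at
high depth. Genomic selection in these crops therefore involves decisions
that diploid pipelines never face: whether to call (and trust) dosage,
which relationship matrix to build from it, and whether mapped QTL
haplotypes add predictive value. `polyGS` implements that full decision
space with a simulator able to generate data under known truth.

# The prediction model

All prediction modes fit the linear mixed model

$$ y = 1_n\mu + u + e,\qquad u \sim N(0, \sigma_a^2 K),\qquad
   e \sim N(0, \sigma_e^2 I), $$

where `y` holds one adjusted mean (BLUE) per genotype and `K` is a genomic
relationship matrix. The intercept is the only fixed effect; stage-1
phenotypic analysis (experimental-design effects, G×E covariances) is out
of scope — the package consumes its output.

## Restricted maximum likelihood

`fit_gblup()` profiles both variance components out of the REML likelihood
through one eigendecomposition of `K`: with `K = U D U'`, the likelihood at
variance ratio λ = σ²ₐ/σ²ₑ needs only O(n) arithmetic, and λ is found by
Brent search on log λ ∈ [−10, 10] (tolerance 1e−8, deterministic). The
boundary fit σ²ₐ = 0 is evaluated explicitly and returned — flagged, not
errored — when it dominates; `K ∝ I` makes the ratio unidentifiable
(likelihood flat in λ) and is flagged as such. Variance components are
never reported negative. The spectral trick makes per-fit cost one
eigendecomposition, which is what keeps 1000-replicate cross-validation
affordable.

`fit_two_kernel()` (for QTL + background models) cannot use one spectral
decomposition; it profiles σ²ₑ and runs Nelder–Mead on the two log variance
ratios from up to five deterministic starting points (2000 evaluations
each), then compares against each single-kernel boundary fit. Identical
kernels make the split non-unique; the fit is flagged and only the sum is
interpretable.

## Prediction and model assessment

Holdout genotypes are predicted by
`û_ho = K_{ho,tr}(K_{tr,tr} + (σ²ₑ/σ²ₐ)I)⁻¹(y_tr − μ̂)`, which equals the
corresponding subvector of Henderson's mixed-model equations on the
combined set (asserted against that oracle in the tests). Predictive
ability (PA) is the Pearson correlation between holdout phenotypes and
GEBVs over `round(0.2 n)`-sized random holdouts; kinships are built once on
all individuals and only phenotypes are masked — the mild information
sharing inherent to standard G-BLUP cross-validation. Per-replicate PAs are
Fisher-Z transformed, models are compared by one-way ANOVA on Z with Tukey
HSD letters at α = 0.05, and each model's average PA is the back-transformed
mean Z. Because tanh is concave on positive z, the back-transformed mean is
slightly *larger* than the arithmetic mean of PA when replicates vary; the
tests assert this direction. Replicates whose predictions are degenerate
(boundary fits) contribute PA = 0 and are counted.

`heritability()` is σ²ₐ/(σ²ₐ+σ²ₑ) on the kinship scale of the fitted model;
`genetic_gain()` is i·σₐ·PA/L per year. The selection intensity defaults to
i = 1 (dimensionless), which is the convention under which the published
summary tables this package reproduces are internally consistent; the
breeding-cycle length L is in years (5 for sweetpotato accelerated
schemes, 8 for potato).

# Relationship matrices

Five kernels cover the gene-action models usually compared:

* `vanraden_additive()` — dosage-additive; markers are centered at `p·q_j`
  and the cross-product is scaled by `p Σ q_j(1 − q_j)`. Under
  Hardy–Weinberg equilibrium this denominator equals the summed dosage
  variances, so REML heritability is calibrated on HWE panels. In a
  biparental F1 the same denominator overstates the genotypic variance and
  ĥ² is inflated (we observe ≈ 0.66 for a simulated target of 0.5); this is
  a property of the estimand, not an estimator defect, so
  parameter-recovery tests use HWE panels.
* `full_model()` — one-hot dosage-class indicators (the auto-hexaploid
  design coding and its tetraploid analogue), centered, normalized to
  trace/n = 1. The normalization constant is a package choice (the usual
  AGHmatrix-style convention); equivalence with other implementations holds
  up to a positive scale factor, which REML absorbs. In populations
  dominated by a single class per marker the off-diagonals collapse; the
  matrix is flagged `quasi_monomorphic` when > 99% of off-diagonal entries
  sit within 1e−6 of their median — such kernels predict poorly, often with
  negative PA.
* `pseudo_diploidize()` + `vanraden_additive()` — the pseudo-diploid model:
  all heterozygous classes collapse to one, discarding dosage.
* `vitezica_dominance()` — orthogonal digenic dominance for diploid-coded
  data; fractional (mean-imputed) dosages interpolate the three codings
  linearly.
* `haplotype_kinship()` — identity-by-descent sharing of parental homolog
  labels in a phased full-sib family: entry (i, j) counts shared labels
  with multiplicity / p, diagonal fixed at 1. The multiplicity rule means a
  double-reduced duplicated homolog counts twice, which is the IBD-correct
  choice.

Missing dosages are mean-imputed per marker inside the builders (which
provably leaves `q_j` unchanged); the I/O layer never imputes. Matrices
whose smallest eigenvalue is below −1e−10 are ridged by |min eigenvalue| +
1e−8 on the diagonal.

# QTL search and QTL-informed prediction

The scan is a deliberately simplified skeleton of random-effect multiple
interval mapping — the full multi-allelic phased QTL model is *not*
re-implemented. On a grid every 2 cM (default), each position contributes a
haplotype kinship, and the evidence for adding a variance component at that
position to the current model is the standardized score statistic

$$ T = \max\!\left(0,\; y'PK P y - \mathrm{tr}(PK)\right) \big/
       \sqrt{2\,\mathrm{tr}\!\left((PK)^2\right)}, $$

with `P` the REML projection of the null model (intercept plus
already-selected QTL kernels, averaged). `T` is invariant to adding a
constant to `y` and to rescaling it. The genome-wide threshold is the
1 − α quantile of the permutation null of the genome-wide *maximum*
statistic (phenotype permutation, 200 draws by default, seeded), so on null
traits the probability of selecting at least one QTL is α by construction —
the calibration the tests verify at α = 0.20, the deliberately relaxed
default appropriate when the goal is prediction rather than QTL discovery.
Selection is sequential-forward; each selected position excludes ±20 cM
(`window_cM`) on its chromosome. The published description does not state
whether "a window of 20 cM" means the half-width or the full span; the
half-width reading (±20) is implemented and exposed as a parameter. An
optional backward pass re-tests each selected QTL against the final model.

`predict_mode()` wires the scan into cross-validation without leakage: the
search re-runs inside every training fold and never sees holdout
phenotypes (asserted by a permutation test). The three modes are G-BLUP
(average of all grid kinships — haplotype-based, following the map-based
formulation), Q-BLUP (average of QTL-peak kinships, G-BLUP fallback when
the fold selects none), and Q+G-BLUP (two kernels: QTL average plus the
average of the non-selected grid positions).

# The simulator

`simulate_f1_family()` emulates the structure the analysis assumes for a
biparental full-sib polyploid family: phased parental haplotypes, random
bivalent pairing (each meiosis pairs the p homologs uniformly at random
into p/2 bivalents and transmits one recombinant product per bivalent —
which at any single locus reproduces the hypergeometric gamete-dosage law),
Haldane recombination along a multi-chromosome map, and optional double
reduction as a single probability α ∈ [0, 0.25]: with probability α a
gamete duplicates one of its sampled alleles (`gamete_pmf()` gives the
closed form; at the sequence level one meiotic product replaces another,
a whole-product approximation). No preferential pairing, no mixed
disomic/polysomic behavior, no multi-generation pedigrees. Homolog origin
is recorded per marker so haplotype kinships are exact IBD, not inferred.

`simulate_panel()` draws unrelated individuals under polysomic HWE,
dosage ~ Binomial(p, q). Default frequencies follow Beta(1.2, 6) truncated
at 0.03, giving a realized mean minor allele frequency near 0.15 — the
shape typical of hard-filtered GBS diversity panels. F1 founder frequencies
default to Uniform(0.05, 0.5).

`attach_phenotype()` samples QTL among markers, builds additive values from
per-copy effects, optionally adds digenic (`x(p − x)` scaled) or
full-class (arbitrary value per dosage class) non-additive terms, and sets
the residual variance so the realized narrow-sense h² matches the target
(verified to ±0.05 at n ≥ 300 averaged over seeds); `target_h2 = 0` yields
pure noise. When the requested non-additive variance exceeds what the
target h² allows, the residual clamps at zero with a warning.

`degrade_by_depth()` emulates naive genotyping-by-sequencing calling: depth
~ Poisson(mean reads/locus), alternative reads ~ Binomial(depth, d/p),
call = maximum-likelihood dosage under the binomial read model with a
uniform prior (ties break toward the lower dosage, a deterministic
convention), zero depth → missing, plus completely-at-random missingness.
There is deliberately no population prior and no base-error model: the
point is to reproduce the depth/accuracy trade-off of naive callers, under
which heterozygous-class error rises steeply below ~100× depth.

What passing tests on these simulations do **not** show: robustness to
preferential pairing or segregation distortion, to map error, to
population structure beyond a single family or an unstructured panel, or
to non-Gaussian phenotypes. Conclusions about real breeding data need the
real data.

# Numerical and design choices

* Holdout size is `round(n × fraction)` (rounding convention made
  explicit).
* Negative per-replicate PAs are retained; Fisher-Z handles them.
* Splits are shared across models within a comparison — a paired design
  that sharpens model contrasts.
* Tukey HSD letters come from an insert-and-absorb pass over the pairwise
  p-value matrix, models ordered best-first.
* All randomness flows from user-supplied integer seeds; simulation,
  splitting, permutation and subsampling are bit-reproducible.
* Filter thresholds are inclusive (≥), and minor allele frequency is
  computed by counting alleles in dosage genotypes on one code path for
  every ploidy, including pseudo-diploidized data.
* Marker informativeness is reported as expected heterozygosity
  `1 − q² − (1 − q)²` (range 0–0.5), not the stricter multi-allele PIC
  bound.

Problem sizes in the test suite are chosen for a single-CPU desk run:
families of 120–500 individuals, 60–150 markers over 1–2 chromosomes,
grids of 5–10 cM, 10–200 cross-validation replicates, and 60–120
permutations per scan; the statistical contracts they check (oracle
equalities, null calibrations, parameter recovery, model rankings) are
size-invariant.

# Limitations

Single-trait, single-kernel-pair models only: no multi-trait or G×E
kernels, no marker-effect (RR-BLUP) parameterization, no Bayesian
variable-selection models. No pedigree or blended matrices. The QTL scan
reports positions and variance evidence, not effect estimates. VCF import
handles biallelic GT/GQ/DP fields only, and variant calling from reads is
upstream of this package.
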