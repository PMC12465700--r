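---
title: "Transcriptome-integrated genomic prediction with weighted multiple-kernel ridge regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-integrated genomic prediction with weighted multiple-kernel ridge regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmkrr)
```

## The prediction problem

In breeding programs, most reference animals have genotypes but no
transcriptome: RNA sequencing is expensive and some tissues cannot be
sampled in vivo. Gene expression nevertheless carries information about
complex traits that plain additive SNP models miss. A practical middle
road is to *predict* expression from cis-SNPs — many genes are strongly
cis-regulated — and let a prediction model decide, per trait, how much
weight the (predicted) transcriptome deserves next to the genome. `wmkrr`
implements that decision as multiple-kernel learning inside kernel ridge
regression, plus everything needed to validate the machinery on synthetic
data with known truth.

## Models

### Kernel ridge regression and kernel fusion

KRR minimizes `½‖β‖² + (1/2λ) Σ (y_i − β′φ(x_i))²` in an implicit feature
space and never materializes `φ`; the dual solution is
`α = (K + λI)⁻¹y` and a new sample is predicted as `y(x) = k′α` with `k′`
its similarity vector to the training samples. Because a weighted sum of
kernels is again a kernel, two data sources combine as

`K = w₁·K_a + (1 − w₁)·K_b`

with `K_a` from genotype dosages and `K_b` from expression values, each
either a linear kernel `XX′` or a Gaussian kernel
`exp(−θ‖x_i − x_j‖²)` (the per-feature product form
`∏_k exp(−θ(x_ik − x_jk)²)` is algebraically the same and is what the
tests check against). Only `w₁` is ever stored; `w₂ = 1 − w₁` by
construction.

Two modelling choices here were genuinely open and are package decisions:

* **Response centering.** The KRR objective carries no intercept while
  the mixed-model comparators include an overall mean μ; `fit_krr()`
  therefore centers `y` by default and adds the training mean back at
  prediction, which also makes the tuned λ interpretable as a
  signal-to-noise ratio (`center_y = FALSE` turns it off). With this
  convention, KRR on the genomic relationship matrix with
  `λ = σ²_e/σ²_g` reproduces GBLUP exactly when G is built from the
  training data's own allele frequencies (zero row sums), which the
  acceptance suite verifies to 1e-6.
* **Feature scaling for kernels.** Distances over tens of thousands of
  raw dosages would saturate a Gaussian kernel and make the useful θ
  range data-dependent. `run_comparison()` therefore column-standardizes
  features with training-set statistics (reused unchanged for validation
  rows) and divides linear kernels and squared distances by the feature
  count, so kernel entries are O(1) and one θ search range
  (`log10 θ ∈ [−6, 1]`) works across panels. This scaling is a deliberate
  deviation knob: `gaussian_kernel()` itself applies no scaling, so users
  can reproduce unscaled behaviour.

### Hyperparameter search

`tune_wmkrr()` follows the classic Bayesian-optimization loop: a random
initial design (default 10 points), a Gaussian-process surrogate refit
after every evaluation, an expected-improvement acquisition
(`EI = (μ−best−ξ)Φ(z) + σφ(z)`, ξ = 0.01) maximized over 1,024 random
candidates, a fixed iteration budget (default 200), and finally the
best-scoring point of the whole trace. The objective is the Pearson
correlation between concatenated held-out predictions and observations in
an inner 5-fold CV whose folds are drawn once per call, so every candidate
is scored on identical partitions and the trace is exactly reproducible
from one seed.

Surrogate details are package choices: an isotropic Matérn-5/2 covariance
on the unit-cube-scaled search space, unit prior variance on standardized
objective values, and lengthscale/observation-noise estimated by marginal
maximum likelihood from two starts. Search ranges default to `w₁ ∈ [0,1]`,
`log10 λ ∈ [−3, 3]` (interpolation to heavy shrinkage), and
`log10 θ ∈ [−6, 1]` on standardized features (near-linear to near-delta
kernels). In linear-kernel mode θ is dropped from the space. A single θ is
shared by both Gaussian kernels by default (`share_theta = FALSE` gives
per-kernel bandwidths). The initial design counts separately from the
iteration budget, so a run evaluates `n_initial + n_iterations` points.

### Mixed-model baselines

GBLUP fits `y = 1μ + g + e` with `g ~ N(0, Gσ²_g)` and the VanRaden
relationship matrix `G = ZZ′ / 2Σp_i(1−p_i)` (dosages centered by `2p_i`);
GTBLUP adds `t ~ N(0, Eσ²_t)` with `E = RR′/m` from per-gene standardized
expression (sample SD, n−1 divisor — the divisor is a package choice, the
standardization formula is standard). Monomorphic SNPs contribute nothing
to either numerator or denominator of G and are dropped with a recorded
count. `p_i` is the frequency of the *stored* allele; it is often called
MAF in this literature but enters the formulas as the coding frequency,
and the two differ for markers whose stored allele is the major one.

Variance components come from AI-REML: average-information Newton steps
with step halving, an EM-REML step whenever an AI step cannot improve the
restricted likelihood, components clamped at `1e-8·var(y)`, and a warning
when the AI matrix is numerically singular (non-identifiable splits, e.g.
an identity kernel). Prediction of unphenotyped individuals uses the
variance projection `û_r = σ²_r K_r[·,obs] V⁻¹(y − 1μ̂)` with
`μ̂ = (1′V⁻¹1)⁻¹1′V⁻¹y` on the observed block — algebraically the
all-individual mixed-model equations with missing records, but well-posed
even when the expression kernel is rank-deficient (`m` genes < `n`
individuals makes `E` singular, so Henderson equations needing `E⁻¹` are
not an option). Tests pin the solution against a naive explicit-inverse
GLS oracle at small n.

Cis-heritability of a gene's expression is estimated by single-kernel REML
on a VanRaden matrix of the SNPs within ±1 Mb of the gene body, after
residualizing expression on an intercept and the first five genotype
principal components. Hidden-confounder factors (PEER-style) are not
estimated here; the covariate matrix accepts externally computed factors
instead.

## The simulator and what it does (not) emulate

The generator's defaults are the reference study conditions, not tuning
dials:

| parameter | default | meaning |
|---|---|---|
| `h2` | 0.8 | trait heritability |
| `m` | 100 | QTL count, sampled without replacement |
| `sigma2_p` | 1 | phenotypic variance |
| `maf_low`, `maf_high` | 0.05, 0.5 | allele-frequency range, `p ~ U` |
| `n_replicates` | 10 | independent QTL draws per run |

Genotypes are `Binomial(2, p)` with independent SNPs on a synthetic 1-kb
map; QTL effects follow `a_i = (2p_i(1−p_i))^{−1/2}·σ_g/√m` with
`σ_g = √(σ²_p·h²)`, computed from each QTL's *realized* frequency in the
marker data (not the generative one); `TBV_i = Σ_k dosage_ik·a_k`;
residuals are `N(0, (1−h²)σ²_p)`; phenotype = TBV + residual. Under this
construction each QTL contributes `σ²_g/m` of variance in expectation, so
realized `var(TBV)/var(phenotype)` concentrates near h² and
`var(phenotype)` near σ²_p — the two quantities the acceptance script
recomputes (at 2,000 × 5,000 × 10 replicates they land within ±0.01 of
0.8 and ±0.02 of 1.0 across seeds). QTL markers stay in the kernel-building
set by default (`eligible_snps` makes the set explicit).

Expression is simulated gene-by-gene on consecutive 10-SNP windows:
cis effects `N(0,1)`, genetic value rescaled to a target cis-h², Gaussian
noise for the remainder. DRP-like pseudo-phenotypes add noise scaled so
that `cor²(DRP, TBV)` approaches a target reliability.

What passing tests on this synthetic world do *not* show: behaviour under
linkage disequilibrium (an optional AR(1) Gaussian-copula block mode
exists precisely because kernel methods are LD-sensitive, but it is off by
default), multi-breed structure, non-Gaussian expression distributions
with high non-expression rates, selection, or pedigree structure. Results
on real data can differ materially on all of these axes.

Every generator derives its stream from a master seed via a labelled
31-bit hash (`derive_seed`), so replicates are independent yet the whole
pipeline is bit-reproducible and partial reruns stay consistent.

## Evaluation protocol

`run_comparison()` executes a 5×10-style repeated CV (or a birth-year
forward split) with one fold plan shared by every method, per-fold
univariate feature selection restricted to training rows (F statistic of
the per-SNP simple regression; stable tie-breaks by file order; default
top-k 30,000), and per-repeat metrics averaged over repeats: predictive
ability `cor(obs, pred)/r̄` (r̄ = 1 for simulated phenotypes, mean DRP
accuracy in DRP mode), the OLS slope of observations on predictions, and
centered RMSE. Undefined metrics (constant vectors) propagate as `NA`,
never as 0. The DRP reliability formulas `ERC = λ_h·REL/(1−REL)` and
`r²_DRP = ERC/(ERC+λ_h)` are implemented verbatim; as printed they compose
to `r²_DRP = REL`, and both intermediates are exposed so users can
substitute their own ERC source. The full deregression of EBVs into DRPs
is out of scope.

## Numerical choices

* All symmetric solves go through Cholesky factorization; no explicit
  inverses in fitting paths. If a factorization fails, diagonal jitter
  escalates from `1e-8·mean(diag)` and the amount applied is recorded on
  the kernel/model object — never a silent pseudo-inverse.
* Kernels are symmetrized at construction (tolerance 1e-10) and Gaussian
  kernels carry an exact unit diagonal.
* Missing dosages are imputed at load to the rounded per-SNP mean and
  counted in the load report (upstream data in this field are normally
  pre-imputed; the policy only exists so loading is total).
* Zero-variance genes are excluded from E (counted), constant SNPs score
  0 in feature selection, and inner-CV folds with constant predictions
  contribute an objective of 0 with a warning.

## Problem sizes used in the shipped checks

The test suite exercises REML recovery at n = 500 with 2,000 SNPs over 20
replicates, kernel-weight recovery over 10 tuner runs (initial design 6,
25 iterations) at n = 300, and the simulator checks at 2,000 × 5,000 —
sizes chosen so the whole suite completes in well under a minute per
module on a single core while keeping Monte-Carlo noise far below the
tested tolerances. The 200-iteration tuning budget remains the package
default for real analyses.

## Known limitations

* No dominance or epistatic relationship matrices, and no haplotype
  kernels; nonlinearity enters only through the Gaussian kernel.
* The elastic-net expression predictor is a straightforward cis-window
  model, not a nested-CV model database; it exists so the full
  genotype → predicted-expression → prediction pipeline can be exercised
  end to end.
* Forward validation assumes `birth_year` is complete for validation
  candidates.
* AI-REML reports, rather than resolves, non-identifiable variance
  splits.
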