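---
title: "Models, assumptions and design choices in mrmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in mrmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmetab)
```

# Scope

`mrmetab` implements a two-stage analysis of the fasting plasma metabolome
in relation to insulin resistance (IR) and impaired insulin secretion: an
observational metabolome-wide association scan with FDR control, and
Mendelian randomization (MR) of genetic risk scores on metabolite levels
with a full sensitivity suite. This vignette documents the statistical
models, the assumptions they rest on, the tunable parameters, and the
design decisions taken where the methodology was genuinely open. Everything
quantitative claimed here is computed by the test suite or the acceptance
script; nothing is asserted beyond what those runs show.

# Stage 1: outcomes and the association scan

## Physiologic outcomes

Three outcomes are derived per individual:

* **Clamp M/I** — glucose disposal per unit plasma insulin during a
  hyperinsulinemic-euglycemic clamp, in
  mg · kg⁻¹ body weight · min⁻¹ per mU/l × 100. Must be positive.
* **IGI30** — the insulinogenic index,
  `(ins30 − ins0) / (glu30 − glu0)` over 0–30 min of an OGTT. Samples with
  zero glucose change are undefined and excluded with a logged reason.
* **DI** — the disposition index, `clamp M/I × IGI30`, β-cell
  responsiveness adjusted for sensitivity.

IGI30 and DI are log-transformed toward normality. Noisy OGTT data can
produce non-positive IGI30/DI; such samples are excluded from the log
outcomes, with each exclusion and its reason recorded in an attribute
(`derive_outcomes()`). All analysis copies are standardized to mean 0,
SD 1.

## The scan

`metabolome_scan()` fits one OLS model per metabolite — outcome on
metabolite plus covariates — and reports the metabolite coefficient with a
two-sided p-value from the t distribution at the residual degrees of
freedom (not the normal: at n in the hundreds the difference is visible in
the tails). When no values are missing the scan uses a shared-design
partial-regression fast path that is algebraically identical to the full
fit (verified against `lm()` in the tests). Benjamini–Hochberg q-values
are appended over the scan, with rejection at q ≤ 0.05 by default; the BH
computation delegates to `stats::p.adjust`. Coefficients can be reported
in the direction of worsening IR / impaired secretion (`flip_sign`), a
pure sign convention that the tests pin down.

Covariates are a user-supplied block (age by default in the pipeline;
"sample quality" indicators in real cohorts are study-specific and
therefore not hard-coded). BMI enters only when `adjust_bmi = TRUE`, so
that adiposity-mediated associations can be compared with and without it.

# Stage 2: Mendelian randomization

## Genetic risk scores

`build_score()` computes the additive unweighted score
`score_i = Σ_j dosage_ij` under three rules: (a) score SNPs absent from
the genotype data contribute the constant `2·RAF` from the reference
frequency in the score definition; (b) individuals missing exactly one
genotyped value have it replaced by that SNP's sample-mean dosage,
computed from the post-harmonization non-missing dosages in the analysis
cohort (the natural choice; which mean to use is not standardized); (c)
individuals missing more than one value are excluded. Frequency-imputed
SNPs are constants and do not count toward rule (c). SNPs with call rate
≤ 95% trigger a warning naming the SNP.

`harmonize_alleles()` orients dosages to the risk allele, flipping
`d → 2 − d` when the file counts the other allele and raising an error on
incompatible allele sets. Palindromic (A/T, C/G) SNPs cannot be oriented
from labels alone; they are resolved by comparing the counted-allele
frequency in the file with the declared risk-allele frequency, and
excluded as unresolvable when either frequency falls within ±0.08 of 0.5.
The window is configurable; 0.08 keeps resolution decisive for the allele
frequencies typical of validated score SNPs while refusing genuinely
ambiguous cases.

## The Wald ratio and its standard error

With `β̂_GM` (score–metabolite) and `β̂_GX` (score–exposure), both from
linear models with SD-unit traits,

```
β_IV  = β̂_GM / β̂_GX,
SE_IV = |β_IV| · sqrt((SE_GM/β̂_GM)² + (SE_GX/β̂_GX)²),
```

the first-order delta method for a ratio of independent estimates. 95%
intervals and p-values use the normal approximation with
z = 1.959964 throughout — at study sizes in the thousands the t correction
is negligible and published symmetric CIs follow this convention.
`p_from_estimate_ci()` inverts it, recovering a two-sided p from a printed
estimate and CI; three published estimate/CI/p triples reconstruct to
their printed precision in the acceptance tests.

Two degenerate cases are handled explicitly: a zero exposure association
is a weak-instrument error (the ratio is undefined), while a zero
metabolite association returns `β_IV = 0` with the analytic limit
`SE_IV = |SE_GM / β̂_GX|` and a flag — the SE formula above is undefined
there but the estimator itself is well-behaved.

**Independence matters.** The delta-method formula assumes the numerator
and denominator are estimated from independent samples — the two-sample
design in which exposure associations come from an external GWAS and
metabolite associations from the analysis cohorts. The validation
replicates therefore use that design. In a one-sample layout the two
estimates share sampling error; we measured 95% CI coverage of about 0.974
there (conservative, because the ignored covariance term is negative on
net), against 0.95–0.96 in the two-sample layout. The same shared-error
mechanism biases MR-Egger's slope in one-sample data, which is why the
per-SNP sensitivity inputs also pair an external exposure GWAS with
cohort-level outcome associations.

## Summary-statistic score association and meta-analysis

`summary_score_assoc()` combines per-SNP GWAS effects into the
score–trait association, `α = Σ wβ/s² / Σ w²/s²`,
`SE = (Σ w²/s²)^(-1/2)`, with unit weights for the unweighted score. With
one SNP it returns that SNP's `(β, s)` unchanged; in the zero-noise limit
it equals the exact linear-combination effect — both pinned by tests.
`meta_fixed()` pools study estimates by fixed-effects inverse variance;
it is exactly associative (nested pooling equals flat pooling to 1e-12)
and is cross-checked against `metafor::rma(method = "FE")`.

## Sensitivity estimators

All operate on per-SNP pairs `(bx_j, sx_j, by_j, sy_j)`:

* **Per-SNP Wald ratios** `θ̂_j = by_j/bx_j` with first-order
  `se_j = sy_j/|bx_j|`.
* **IVW**: `θ̂ = Σ bx·by/sy² / Σ bx²/sy²` with fixed-effect
  `SE = (Σ bx²/sy²)^(-1/2)` — algebraically identical to inverse-variance
  pooling of the per-SNP ratios (tested to 1e-12). A multiplicative
  random-effects option inflates the SE by `max(1, sqrt(Q/(J−1)))`.
* **MR-Egger**: weighted least squares of `by` on `bx` with an
  unconstrained intercept, weights `1/sy²`, after re-orienting every pair
  to `bx > 0`. The intercept estimates average directional pleiotropy and
  is consistent under InSIDE (instrument strength independent of direct
  effects); the slope is the causal estimate. SEs carry a multiplicative
  residual scale bounded below by 1, p-values use t with J−2 df (a normal
  option exists, as published conventions differ). The lower bound plus
  the t reference make the intercept test deliberately conservative: with
  10 instruments the measured type-I error is ≈ 0.02 at α = 0.05.
  Constraining the intercept to zero reproduces IVW exactly.
* **Likelihood estimator** (`mr_likelihood()`): the measurement model
  `bx_j ~ N(ξ_j, sx_j²)`, `by_j ~ N(θξ_j, sy_j²)`, independent across
  SNPs, which — unlike IVW — accounts for sampling error in the exposure
  associations. The nuisance ξ profile out in closed form, leaving the
  one-dimensional objective `Σ (by − θbx)²/(sy² + θ²sx²)`; it is
  minimized by Brent search over three dispersed bracketing intervals
  around the per-SNP-ratio spread (deterministic; a boundary solution is
  a convergence error). The SE comes from the curvature of the profile
  log-likelihood at the maximum (central differences). Against an
  independent brute-force oracle — a θ grid with numerical inner
  optimization over each ξ_j — 100 random 10-SNP instances agree to
  better than 1e-6.
* **Cochran's Q** over the per-SNP ratios against the IVW pooled
  estimate, df = J−1, chi-square p. Under homogeneous simulation its mean
  matches df.
* **Diagnostics**: scatter (by vs bx), funnel (θ̂_j vs 1/se_j) and
  leave-one-out IVW tables. Leave-one-out exists to surface single
  anomalous instruments (the classic case being a variant associated with
  the exposure in the unexpected direction); the tests confirm it ranks a
  displaced instrument first.

All estimators are equivariant under rescaling of the exposure
associations (multiplying bx, sx by c divides estimates by c), tested as
a property.

# The synthetic-data generator

The generator defines the conditions under which the machinery is
validated, so its structure is documented precisely:

* **Genotypes**: independent SNPs in Hardy–Weinberg equilibrium,
  `dosage ~ Binomial(2, RAF)`; no linkage disequilibrium, because score
  variants sit on distinct loci and are treated as independent
  instruments.
* **Exposure**: `X = Σ a_j G_j + b_U·U + e`, standardized to SD-units.
  `U ~ N(0,1)` is a single shared confounder — the minimal structure that
  makes observational and MR estimates diverge. Default instrument: 10
  SNPs, RAF 0.2–0.5, per-allele effects 0.05–0.15 SD, explaining ≈ 5% of
  exposure variance (first-stage F ≈ 250 at n = 5,000). Published scores
  do not report their variance explained, so this is a tunable default,
  not a claim about any cohort.
* **Metabolites**: `M_k = θ_k X + c_M U + Σ d_jk G_j + ε`, standardized.
  `θ` is the causal effect MR should recover; `d` injects directional
  pleiotropy. Residual SDs default to a unit-population-variance
  calibration (the residual absorbs whatever variance the structural terms
  leave), so that effects are genuinely per-SD on both sides and empirical
  standardization is a near-identity.
* **Physiology**: OGTT insulin/glucose and clamp M/I are monotone
  transforms of latent sensitivity (−X) and secretion variables, centred
  on values typical of elderly non-diabetic cohorts (clamp M/I ≈ 5.4,
  DI ≈ 2.5), so derived IGI30/DI carry the assumed sign structure.
* **Feature tables**: log-intensities get plate-level random intercepts
  and a linear injection-order drift — additive batch structure on the log
  scale — plus optional duplicate injections and pure-noise features.
* **Summary statistics**: per-SNP true marginal effects follow from the
  model (`a_j/sd(X_raw)` for the exposure; `θ·a_j/sd(X_raw) + d_j` for a
  metabolite), reported with noise `N(0, se)` at
  `se = 1/sqrt(2 f(1−f) n_gwas)`; `n_gwas = Inf` is the zero-noise limit.

What the generator does **not** emulate: linkage disequilibrium,
imputation quality, realistic mass-spectral peak shapes, non-Gaussian
metabolite distributions, or population stratification. Passing tests
therefore demonstrate correctness of the estimators under their stated
assumptions, not robustness to every pathology of real cohort data.

# Preprocessing

The feature-QC pipeline applies, in a fixed order: natural-log transform
(zeros replaced by half the feature's minimum positive value — a
configurable pseudo-count; the convention is not standardized),
ANOVA-type standardization (per-feature linear model on categorical batch
factors plus a linear acquisition-order drift term; residuals plus grand
mean, which equalizes per-plate means exactly and is idempotent),
then filtering: retention time < 35 s → removed; inter-duplicate Pearson
correlation (log scale, pairwise-complete) below 0.5 → removed; values
beyond 3 sample SDs of the feature mean → masked missing; features with
too few non-missing values after masking → removed. Masking rather than
dropping at the outlier step matters: the non-missing-count rule is
defined on the post-masking table. Every removal appears exactly once in
the report with its reason. SDs are sample SDs (n−1) throughout. The 0.5
duplicate-correlation default is an explicit choice where published
pipelines say only "low".

# Problem sizes and numerical choices

The validation suite uses 500 replicates at n = 5,000 for Wald recovery,
coverage, null calibration and pleiotropy recovery; 200 replicates of a
300 × 200 scan with 20 true signals for FDR control; and 100 random
instances for the likelihood oracle — sizes at which Monte-Carlo error is
small relative to the tolerances being asserted while the whole suite
completes in minutes on one CPU. Fixed numerical conventions:
z = 1.959964 for all 95% intervals; optimizer tolerance
`.Machine$double.eps^0.5` with three bracketing intervals for the
likelihood estimator; 1e-12 for algebraic identities; BH q-values from
`stats::p.adjust`.

# Known limitations

* One-sample MR is supported mechanically but its correlated-error
  effects (coverage, Egger slope bias) are the user's to weigh; the
  estimators assume the two-sample design.
* No weighted-median or mode-based estimators, no correlated-instrument
  (LD-aware) generalizations, no bidirectional or multivariable MR.
* The likelihood estimator supports only independent exposure/outcome
  sampling errors (`rho = 0`).
* LD-based proxy discovery, spectral processing and metabolite annotation
  are out of scope; proxies and annotations are taken as given.
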