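---
title: "Methods: polygenic scoring and the within-sibling decomposition"
author: "sibscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring and the within-sibling decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimand and why siblings matter

A population regression of an outcome on an individual's polygenic
score (PGS) estimates a mixture of effects. Writing $S_i$ for the
child's standardized true score and $\bar S_{p(i)}$ for the midparent
score (the average of the two parents' standardized scores), the
generative model used throughout this package is

$$ Y_i = \beta_d\, S_i + \beta_n\, \bar S_{p(i)} + F_{f(i)} + e_i, $$

with a family-level environment $F_f \sim N(0, \sigma^2_F)$ and noise
$e_i \sim N(0, \sigma^2_e)$. Under random mating the midparent score
has variance $1/2$ on the child scale and
$\mathrm{Cov}(S, \bar S_p) = 1/2$, so the population regression slope
converges to $\beta_d + \beta_n/2$: genetic nurture inflates the
apparent effect of one's own genotype. Within a sibship, $\bar S_p$ and
$F_f$ are constant, and sibling differences in $S$ arise only from
random segregation at meiosis; the within-sibling slope therefore
estimates $\beta_d$ alone. The attenuation

$$ 100 \cdot \frac{\beta_\text{within} - \beta_\text{between}}
               {\beta_\text{between}} $$

equals $100\,(\beta_d - (\beta_d + \beta_n/2))/(\beta_d + \beta_n/2)$
analytically, e.g. $-42.9\%$ for $\beta_d = 0.2$, $\beta_n = 0.3$. The
same cancellation protects the within estimate from population
stratification (systematic allele-frequency differences tied to
environment) and from assortative mating.

## PGS construction

`qc_filter()` removes strand-ambiguous variants (allele pair A/T or
C/G, unresolvable without strand information) and keeps variants with
MAF > 0.01 and INFO > 0.8. The inequalities are strict, matching the
usual "MAF > 1%, INFO > 0.8" phrasing; boundary values are removed.

`harmonize()` intersects on variant id and aligns the sign of each
weight to the genotype's counted allele (the ALT allele throughout);
disagreeing allele pairs are dropped and counted. `ld_clump()`
implements the greedy procedure: take the remaining variant with the
smallest p-value as index, remove neighbours on the same chromosome
within 250 kb whose dosage $r^2$ with the index exceeds 0.1, repeat.
Ties on p break by (chromosome, position, id), which makes the output
independent of input row order. Clumping precedes thresholding
(clump-then-threshold); a threshold-specific clump would change variant
counts but not the aggregation logic.

`pgs_score()` computes, for each of the 11 p-value thresholds
(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1), the
dosage-weighted sum over variants with $p \le$ threshold (inclusive),
then z-scores each column. Missing dosages are mean-imputed per variant
at scoring time — a declared default, switchable by pre-imputing the
`genotype_set`. A threshold with no variants yields an all-zero column
and a warning rather than an error, so sparse summary files degrade
gracefully.

`pgs_pca()` aggregates the 11 z-scored columns by their first principal
component. Because the columns are standardized, this is PCA on the
correlation scale. The PCA sign is arbitrary, so the component is
aligned to correlate positively with the across-threshold mean: a
higher final score always means a higher polygenic load. The final
score has mean zero by construction; analyses z-score it within each
analysis sample, so only its direction matters.

## Biomarker harmonization

`adjust_for_medication()` applies the standard back-corrections for
treated individuals — LDL / 0.7 and triglycerides / 0.8 under
cholesterol-lowering medication, +15 / +10 mmHg systolic/diastolic
under blood-pressure medication — and sets glucose and HbA1c missing
under diabetic medication, where no reliable back-correction exists.
The operation stamps a provenance attribute and refuses to run twice,
because accidental re-application is silent data corruption otherwise.
Negative biomarker values abort with a unit-problem error.

`remove_outliers()` is deliberately a *single pass*: the mean and SD
are computed once over non-missing values and points more than 4 SD
away are set missing. An iterated rule would remove more points; the
single pass is the literal reading of a "±4 SD of the mean" rule and is
what the reports count. A zero-SD series removes nothing.

`transform_and_standardize()` then log-transforms the listed
right-skewed biomarkers (natural log; the base is irrelevant after
z-scoring) and z-scores every continuous measure. Non-positive values
under the log become missing and are counted. The fixed order —
medication adjustment, outlier removal, log, z-score — is asserted by
the pipeline. Z-scores are recomputed within each analysis sample
(e.g., within the sibling subsample), a choice the association layer
applies automatically.

`derive_any_disease()` ORs component indicators, treating a missing
component as 0 unless every component is missing. The alternative
(propagate any missing) discards people with partial questionnaires who
affirmatively reported one disease, which is the wrong trade-off for
presence indicators.

Education categories map to 1 / 7 / 10 / 13 / 20 years; "low"
attainment covers everything through secondary schooling, "high" the
two 20-year categories.

## Association models

`fit_glm()` fits identity-link models by least squares and logit
models by IRLS run to a gradient norm below 1e-8 (at most 100
iterations). Collinear columns are dropped via the QR decomposition
with a warning; a coefficient exceeding 15 on the logit scale flags
probable perfect separation and the result is reported non-estimable
rather than as a spurious huge odds ratio.

`sandwich_se()` computes the cluster-robust covariance
$B^{-1} M B^{-1}$ with $B$ the information (bread) and $M$ the sum over
families of outer products of within-family score sums, times the
finite-cluster correction $G/(G-1)$. This working-independence GLM plus
sandwich reproduces the estimand and SE treatment of a GEE with
independence working correlation while needing far less machinery; with
hundreds of families the difference from richer working correlations is
negligible for the point estimate, and the sandwich is valid
regardless. Confidence intervals are Wald, $\pm 1.96\,\mathrm{SE}$.

`nagelkerke_delta_r2()` uses
$R^2 = \left(1 - e^{2(\ell_0 - \ell_1)/n}\right) /
       \left(1 - e^{2\ell_0/n}\right)$
with $\ell_0$ the intercept-only log-likelihood, and reports the
difference between the full model (covariates + PGS) and the
covariates-only model. Identity-link models report the plain $R^2$
difference.

`run_association()` is complete-case per outcome, refuses analyses
with fewer than 50 complete cases, z-scores the exposure (and, for
identity links, the outcome) within the analysis sample, and prunes
covariate terms that are constant in that sample — so a
single-genotyping-chip subsample silently loses the chip and chip×PC
terms without changing the exposure estimate. Stratified analyses
split age at 60 with 60-year-olds in the "older" stratum (the
convention is logged; the boundary phrasing "younger/older than 60" is
ambiguous). `bh_fdr()` validates and delegates to the standard step-up
adjustment; the pipeline applies one combined family across all tests
of a run, mirroring pooled main-plus-secondary correction, with a
per-table option.

## Sibling models

`build_sibships()` groups individuals sharing both (non-missing)
parents and keeps groups with at least two analysable members;
half-siblings never form a stratum. The between-sibling reference is
the population model refit on the sibling subsample — not the
family-mean regression — so that attenuation reflects the design, not a
change of estimand or population.

For continuous outcomes, `fit_within_linear()` demeans outcome and
regressors within sibship (absorbing the family fixed effects) and
fits least squares, with a sibship-clustered sandwich whose
degrees-of-freedom correction accounts for the absorbed means. On sib
pairs this is algebraically the pair-difference regression, which the
tests assert exactly. Family-constant covariates are absorbed and
dropped with a log message.

For binary outcomes, `fit_within_logistic()` maximizes the conditional
likelihood given the number of cases per sibship; family intercepts
cancel, and outcome-concordant sibships contribute nothing (they are
counted and reported). The denominator uses the recursive polynomial
algorithm, so large sibships need no exhaustive enumeration —
enumeration appears only in tests as an oracle. Newton-Raphson runs to
a gradient norm below 1e-8 with a step cap of 5 on the log-odds scale;
the linear predictor is centered within each stratum before
exponentiation for numerical stability. The SE comes from the observed
information of the conditional likelihood.

`compare_between_within()` fits the joint decomposition model — outcome
on sibship-mean PGS and within-sibship deviation plus covariates, with
sibship-clustered sandwich covariance — and Wald-tests equality of the
two coefficients. This construction was chosen because it tests the
null of interest (no between-family confounding) in one model with a
proper covariance; a z comparison of two separately fitted coefficients
ignores their covariance and is reported only as a secondary statistic.
When the two coefficients are numerically identical the test returns
p = 1 directly, guarding a 0/0 in degenerate noise-free data.

## The simulator: what it emulates, and what it does not

`sim_config()` holds the generative conditions. Defaults encode the
study conditions used across the tests: 2 siblings per family,
$\beta_d = 0.2$, $\beta_n = 0.3$, shared-environment variance 0.1,
residual variance 0.755 (unit outcome variance under random mating),
disease prevalences 30% (metabolic) and 5% (cardiovascular), GWAS
noise SE 0.01 around true log-odds weights of SD 0.05, 5% ambiguous
variants, 2% low-MAF, 2% low-INFO, 5% flipped-allele rows.

Design choices, each made once:

- **LD** via a thresholded AR(1) Gaussian latent process within blocks
  (lag-1 correlation `within_block_rho`, blocks laid 1 Mb apart on 22
  autosomes so the clumping window never spans blocks). This gives
  tunable, simple $r^2$ structure — enough to exercise clumping —
  without pretending to be a human LD map.
- **Transmission**: each offspring receives one parental haplotype per
  block from each parent, chosen uniformly; no recombination within
  blocks. Expectation laws (child dosage = midparent dosage on
  average, sib PGS correlation 1/2) hold exactly.
- **Assortative mating** by deterministic rank-matching: spouse
  liability proxies (standardized parental true scores) achieve the
  requested correlation without rejection sampling, so results are
  reproducible from the seed.
- **Binary outcomes** by thresholding a fresh liability at the
  (1 − prevalence) empirical quantile: prevalence is controlled
  directly, unlike logit generation where it depends on the intercept.
- **Stratification**: with two subpopulations the counted allele is
  more frequent in subpop 2 by `freq_divergence`; setting
  `freq_divergence_aligned` makes a fraction of variants diverge in
  the *risk* direction instead, which creates a systematic
  PGS-subpopulation correlation. Without alignment the correlation has
  a random sign and magnitude (weights have random signs), which is
  realistic for drift but useless for demonstrating confounding
  reliably; the stratification scenario uses a 25% aligned fraction
  plus `subpop_env_shift` for the environment side of the confound.
- **Seeds**: one master seed; every stochastic stage (founders,
  pedigree, transmission, summary stats, phenotypes) draws from a
  named substream via `substream_seed()`, so stages can be re-run
  independently and reruns are bit-identical.
- Ambiguous allele pairs are assigned at variant creation and shared
  by genotypes and summary statistics, because harmonization would
  otherwise drop them as mismatches before QC could see them.

The simulator does **not** emulate: realistic LD maps or imputation
(INFO values are labels for QC, not the result of imputing), sex
chromosomes, three-generation chains, self-report measurement error in
disease indicators, or medication effects beyond flagging the upper
tail of a biomarker. Passing tests therefore demonstrate correctness
of the estimators under the stated generative model, not robustness to
every feature of real cohort data. The additive generative model
itself is an idealization chosen for testability — real
PGS-outcome links need not be linear or homogeneous.

## Score measurement error and the recovery experiment

The constructed PGS is a noisy proxy for the true score; its
correlation with the truth falls with GWAS noise, QC losses of causal
variants, and clumping under LD. Measurement error attenuates the
within-sibling slope *more* than the population slope (the deviation
component has the lower signal-to-noise), so attenuation percentages
computed from noisy scores overshoot the analytic value — visible in
the README example. The recovery experiment in the acceptance
script and tests therefore uses independent variants, a clean
summary-stat file (no QC-failing fractions) and GWAS SE 0.005, giving
score-truth correlations above 0.99, so that it measures the
estimators rather than the proxy error; QC and clumping behaviour are
tested separately where they are the subject.

## Problem sizes and numerical conventions

Test and acceptance runs use: 5,000 families × 2 siblings × 800
variants for direct-effect recovery; 500 replicates of 400 families
for null calibration of the comparison test (Kolmogorov–Smirnov
uniformity); 500 replicates of 100 clusters × 4 members at ICC 0.5 for
sandwich coverage; 1,500 families × 400 variants for the
stratification scenario. These sizes put Monte-Carlo error well inside
the 3-SE assertions while keeping the full suite under half a minute.

Conventions collected in one place: coordinates are 1-based (VCF);
clumping windows are $|pos_i - pos_j| \le 250{,}000$; score membership
is $p \le$ threshold; QC cuts are strict inequalities; the counted
allele is ALT; ORs are $e^{\hat\beta}$ with Wald CIs; age 60 belongs to
the older stratum; "any disease" treats missing components as 0 unless
all are missing; the 4-SD rule is single-pass; logs are natural.

## Known limitations

Conditional-logistic SEs are observed-information, not additionally
clustered across sibships (each sibship is one stratum, so residual
between-stratum correlation is not modelled). The comparison test's
construction (Wald on the joint decomposition) is one reasonable
formalization of "compare between and within coefficients"; other
constructions exist and can differ in small samples. Binary-outcome
generation is liability-threshold only. The pipeline's FDR family is
defined per run; combining runs requires recomputing the adjustment
over the union of tests.
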