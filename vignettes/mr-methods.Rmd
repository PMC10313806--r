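---
title: "Two-sample Mendelian randomization of PTSD traits and ischemic stroke: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdstrokemr)
```

## The question and the design

Observational studies associate post-traumatic stress disorder (PTSD) with
ischemic stroke (IS), but confounding makes the causal direction hard to
pin down. Two-sample Mendelian randomization (MR) sidesteps much of that:
genetic variants associated with a PTSD trait are used as instrumental
variables, their effects on the exposure ($\gamma_i$, per SD of the trait)
taken from one GWAS and their effects on stroke ($\alpha_i$, log odds)
from an independent GWAS with no sample overlap. Under the instrumental
assumptions — the variant associates with the exposure, shares no
confounder with the outcome, and affects the outcome only through the
exposure — the per-variant ratio $\alpha_i/\gamma_i$ estimates the causal
log odds ratio of stroke per exposure SD.

This package implements that pipeline end to end: reading and validating
summary statistics, instrument selection, harmonization, estimation,
sensitivity analysis, and bidirectional orchestration — plus a synthetic
summary-statistics generator with known causal structure so that every
stage is testable without the (non-redistributable) consortium data.

## Instrument construction

Three steps, with these defaults:

* **Selection** (`filter_by_pvalue`): SNPs with exposure association
  $P < 5\times10^{-7}$ (strict). The suggestive threshold, rather than the
  genome-wide $5\times10^{-8}$, keeps enough instruments for traits where
  few variants reach genome-wide significance.
* **Clumping** (`clump`): greedy selection of index SNPs by ascending
  p-value, removing neighbours within 1000 kb (closed interval, same
  chromosome) with $r^2 \ge 0.01$. Ties on p-value are broken by
  (chromosome, position, variant ID), so the output is invariant to input
  row order. LD is always a caller-supplied matrix — the package never
  guesses a reference panel; without one, distance alone removes
  (conservative) and a warning is logged.
* **Strength** (`f_statistic`, `instrument_report`): per-SNP
  $F = (\beta/\mathrm{se})^2$, the single-SNP approximation that needs no
  allele frequency or sample size; $F > 10$ for every instrument is the
  conventional weak-instrument screen. A variance-explained formulation
  ($R^2 = 2\,\mathrm{maf}(1-\mathrm{maf})\beta^2$,
  $F = R^2(n-2)/(1-R^2)$) is available when `eaf` and `n` are present.

## Harmonization

`harmonize` aligns each outcome record onto the exposure's effect allele.
Alleles matching in order are `aligned`; swapped coding negates the
outcome beta and complements its frequency (`sign_flipped`);
reverse-complement pairs are strand flips, with or without an additional
swap. A/T and C/G (palindromic) SNPs read identically on both strands, so
allele comparison alone cannot orient them:

* If the minor-allele frequency exceeds **0.40** in either dataset (or a
  frequency is missing), the SNP is dropped as ambiguous. We read the
  study rule "effect allele greater than 40%" as the standard MAF
  ambiguity band — EAF in (0.40, 0.60) — since a one-sided EAF reading
  would keep exactly the mirror-image cases it is meant to exclude. The
  band edge is a parameter (`palindromic_eaf_band`), and the edge itself
  (MAF = 0.40) is retained.
* Outside the band, the two datasets' frequencies orient the strand: if
  they disagree on which allele is minor after the nominal allele-order
  action, the record is additionally strand-corrected.

Matching is by variant ID only — no chr:pos fallback, which silently
breaks across genome builds. Every instrument is accounted for
(retained + dropped = in), and the synthetic generator's corruption
manifest lets the tests check that planted sign and strand flips are
recovered exactly on 100% of non-palindromic records.

## Estimators

All estimators use the inverse-variance weight
$w_i = \gamma_i^2/\mathrm{se}(\alpha_i)^2$.

* **Wald ratio** (`wald_ratio`), the main test with a single instrument:
  $\hat\beta = \alpha/\gamma$, first-order SE
  $\mathrm{se}(\alpha)/|\gamma|$; a second-order delta-method SE that also
  propagates exposure-side uncertainty is available.
* **IVW** (`mr_ivw`), the main method with $\ge 2$ instruments:
  $\hat\beta = \sum_i w_i(\alpha_i/\gamma_i)/\sum_i w_i$, identical to
  weighted least squares of $\alpha$ on $\gamma$ through the origin. (The
  ratio form is implemented with its normalizing denominator; written
  without it the expression is not an estimator.) Fixed-effect SE
  $1/\sqrt{\sum w_i}$; the multiplicative random-effects SE inflates by
  $\max(1, \sqrt{Q/(n-1)})$. Both rows are always emitted — they share the
  point estimate, and published CIs may come from either.
* **MR-Egger** (`mr_egger`, $\ge 3$): weighted regression with a free
  intercept after canonically re-orienting every instrument to
  $\gamma_i \ge 0$ (the fit is invariant to the incoming orientations; the
  intercept is uninterpretable without this). A non-zero intercept
  indicates directional pleiotropy; the slope is the pleiotropy-adjusted
  estimate under InSIDE. SEs carry an overdispersion factor bounded below
  by 1; t-based inference is behind `t_dist`.
* **Medians** (`median_estimator`, $\ge 3$): per-SNP ratios sorted, the
  estimate interpolated where cumulative normalized weight crosses 1/2;
  equal weights (simple) or $w_i$ (weighted, consistent when valid
  instruments hold a weight majority). SE from a parametric bootstrap
  ($\alpha_i, \gamma_i$ resampled from their sampling distributions,
  default 1000 replicates, mandatory seed, bit-reproducible).
* **Cochran's Q** (`cochran_q`): $\sum_i w_i(\alpha_i/\gamma_i -
  \hat\beta)^2$ against $\chi^2_{n-1}$.
* **Odds ratios** (`to_odds_ratio`): $e^{\hat\beta}$ with normal-theory
  95% bounds $e^{\hat\beta \pm 1.96\,\mathrm{se}}$; rounding happens only
  at the presentation layer.

No multiple-testing correction is applied across traits; results are
nominal p-values, as in the study design this mirrors.

### The PRESSO-style global pleiotropy test

`presso_global` ($\ge 4$ instruments) is a simplified
residual-sum-of-squares test. Observed statistic:
$\mathrm{RSS} = \sum_i w_i(\alpha_i - \hat\beta_{(-i)}\gamma_i)^2$ with
$\hat\beta_{(-i)}$ the IVW estimate leaving instrument $i$ out, so each
instrument is scored against a fit it did not influence. The null
distribution is parametric: the null model is a single common slope, so
each simulation redraws *both* sides around it —
$\gamma^*_i \sim N(\gamma_i, \mathrm{se}(\gamma_i))$ and
$\alpha^*_i \sim N(\hat\beta_{\mathrm{IVW}}\gamma_i, \mathrm{se}(\alpha_i))$
— and recomputes RSS, including the leave-one-out fits and weights, on
the simulated data. Two alternatives fail calibration and were rejected
after measurement: centering the draws on the leave-one-out fits
transmits the observed residual spread into the null distribution
(rejection ~0.01 at nominal 0.05), and holding $\gamma$ fixed omits the
exposure-noise component of the observed residuals (~0.07). With both
corrections the measured null rejection rate is 0.04–0.06 across
instrument strengths (`experiment_presso_null`).

The empirical p-value is $(1 + \#\{\mathrm{RSS}^* \ge
\mathrm{RSS}\})/(n_\mathrm{sim}+1)$, never exactly zero. Per-SNP outlier
p-values compare each observed term with its simulated counterparts and
are Bonferroni-flagged; with $n_\mathrm{sim}$ simulations the smallest
attainable p-value is $1/(n_\mathrm{sim}+1)$, so several contaminated
instruments can tie at the floor — the outlier table is therefore ranked
with ties broken by the observed RSS term, and detecting a planted
outlier means it ranks first. The full method's distortion test is not
implemented.

## The synthetic generator

`simulate_pair` emulates the two-sample design this pipeline targets. Per
SNP: $\mathrm{maf} \sim U(0.05, 0.5)$; true effect $\gamma \sim
N(0, \sigma_\gamma^2)$; standard errors follow the standardized-trait
approximation $\mathrm{se} = 1/\sqrt{2N\,\mathrm{maf}(1-\mathrm{maf})}$;
observed effects add independent noise on the two sides (no sample
overlap); the true outcome effect is $\beta\gamma + \delta$ with an
optional pleiotropic $\delta$. P-values are two-sided normal; alleles are
drawn with a configurable palindromic fraction; the outcome file is then
corrupted by allele-coding swaps and strand flips, every change logged in
a truth manifest.

Defaults encode the study conditions being emulated: exposure
$N = 186{,}689$ (the European-ancestry quantitative PTSD traits), outcome
$N = 440{,}328$ (34,217 stroke cases + 406,111 controls), causal effect
$\beta = 0.2$ log-odds per SD. Values the design leaves open were fixed
once as realistic: $\sigma_\gamma = 0.03$ (per-allele effects of a few
percent of an SD, typical for complex traits, giving mostly-strong
instruments at this sample size), corruption probabilities 0.1/0.1, and a
palindromic fraction of 0.15 (A/T + C/G variants are a substantial
minority of genotyping content). A nonzero pleiotropy mean is applied
relative to the exposure-increasing allele (multiplied by
$\mathrm{sign}(\gamma)$): with symmetric $\gamma$ and an unsigned mean,
"directional" pleiotropy would cancel under Egger's canonical
re-orientation, making the concept vacuous in simulation.

Deliberate simplifications, hence what passing tests do *not* show about
real data: binary-outcome effects are generated directly on the log-odds
scale (no liability-threshold model); LD is block-diagonal with constant
within-block $r^2$ and positions on one synthetic chromosome (adequate
for window-based clumping, nothing like real LD decay); no winner's
curse, since selection operates on the same statistics that are
generated; allele frequencies agree between datasets up to small noise
that never crosses 0.5, so frequency-based strand resolution is cleaner
than in cross-ancestry practice.

## Calibration experiments and problem sizes

`simulate_instruments` draws instruments at the summary level (the same
model minus the allele layer) for the estimator calibration experiments,
which use strong instruments ($\sigma_\gamma = 0.3$, $F \sim 10^3$–$10^4$)
so that weak-instrument dilution — a real bias of order $1/F$ — is
negligible against Monte-Carlo error and the experiments measure the
estimators, not the instruments. The shipped experiment sizes: parameter
recovery and 95% CI coverage, $k = 50$, 1000 replicates; type-I error,
2000 replicates; Egger intercept recovery under planted directional
pleiotropy (mean 0.01), 200 replicates; weighted median with a 30%
invalid minority, 200 replicates; PRESSO-style null calibration, 500
replicates at 200 simulations each. Each completes in seconds; all are
re-run from scratch by `scripts/acceptance.R`.

## Degenerate inputs and numerical choices

Zero instruments after filtering or harmonization produce a recorded
failed analysis row, never a crash. A single instrument routes to the
Wald ratio; $\gamma = 0$ is an explicit error. Estimators refuse
instrument counts below their identifiability minimum (2 for IVW, 3 for
Egger and medians, 4 for the global test). All stochastic methods require
an explicit seed and are bit-reproducible under it, restoring the
caller's RNG state afterwards. Confidence intervals use the normal 1.96
approximation throughout, matching how such studies report ORs;
small-sample t inference for Egger is opt-in. Numeric round-trips through
the text formats are exact to better than $10^{-12}$ (15 significant
digits on write).

## Reverse analyses: a caveat the workflow demonstrates

`run_bidirectional` reruns the identical machinery with roles swapped and
the same thresholds (the reverse-direction threshold is an assumption;
the design this mirrors does not state one). In a one-directional
simulation, any SNP whose *mediated* outcome association reaches the
selection threshold becomes a "reverse instrument", and the reverse
estimate then approaches the reciprocal of the forward effect —
`analysis/04_reverse_mr.R` shows this artifact deliberately. Real
analyses guard against it with outcome-specific instruments; Steiger
filtering would automate the guard but is out of scope here.

## Known limitations

Single-trait pairs only (no multivariable MR, CAUSE, MR-RAPS, or
colocalization); no proxy-SNP substitution for instruments missing from
the outcome GWAS; indel alleles are accepted but never strand-resolved;
LD must be supplied, never computed from genotypes; the PRESSO
simplification omits the distortion test. The worked analyses in
`analysis/` run entirely on synthetic data — applying the pipeline to
real consortium files requires only a `column_map` for their headers.
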