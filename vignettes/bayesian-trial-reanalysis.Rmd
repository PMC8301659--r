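---
title: "Bayes factor reanalysis of two-arm trials from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes factor reanalysis of two-arm trials from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialbf)
```

## The problem

When a randomized trial reports a statistically non-significant result, a
frequentist analysis cannot distinguish "the treatment does nothing" from
"the trial was too small to tell". A Bayes factor can: `BF01` quantifies how
much more likely the observed data are under the null hypothesis of no
effect than under a default alternative, so `BF01 = 8` is positive evidence
*for* no efficacy, while `BF01 = 1` means the trial was simply
uninformative. This distinction mattered acutely for the remdesivir
COVID-19 trials, where regulators had to weigh several underpowered and
conflicting studies.

The catch is that reanalysts rarely have raw trial data. What trials
publish is a heterogeneous mix of summary statistics: means with standard
deviations, medians with interquartile ranges, hazard or rate ratios with
confidence intervals, and per-arm event counts. `trialbf` implements the
whole chain from those published summaries to a categorized Bayes factor,
together with a synthetic-trial generator that makes every stage testable
against known ground truth.

## The two-sample t path

### Model

For a continuous (or continuous-like) outcome compared across two arms of
sizes $n_1, n_2$, the evidence model is the Jeffreys--Zellner--Siow (JZS)
default Bayes factor. Writing $\delta$ for the standardized effect size
(mean difference over the common SD), the hypotheses are

$$H_0: \delta = 0, \qquad H_1: \delta \sim \mathrm{Cauchy}(0, r),$$

and for an observed two-sample $t$ with $\nu = n_1 + n_2 - 2$ degrees of
freedom and effective sample size $N = n_1 n_2 / (n_1 + n_2)$,

$$BF_{01} = \frac{f_\nu(t)}{\int f_\nu\!\left(t;\, \delta\sqrt{N}\right)\,
  \mathrm{Cauchy}(\delta;\, 0, r)\, d\delta},$$

with $f_\nu(\cdot;\, \mathrm{ncp})$ the noncentral-$t$ density. The default
scale $r = \sqrt{2}/2$ places half the prior mass on $|\delta| < 0.707$ --
the conventional "medium" default when no prior indication of efficacy
exists. The test is two-sided: only $|t|$ matters.

### Reconstruction of t

Three entry routes produce the `two_arm_comparison` that the Bayes factor
consumes:

* **Mean/SD per arm** -- the classical pooled-variance two-sample $t$.
  Pooled, not Welch, because the JZS factor is defined for the classical
  statistic with $\nu = n_1 + n_2 - 2$.
* **Median and quartiles per arm** -- converted to mean/SD with the Wan et
  al. (2014) estimators, $\hat\mu = (q_1 + m + q_3)/3$ and $\hat\sigma =
  (q_3 - q_1)/\eta(n)$ with $\eta(n) = 2\Phi^{-1}\{(0.75n - 0.125)/(n +
  0.25)\}$. The finite-sample correction $\eta(n)$ matters below $n
  \approx 50$; the crude $(q_3-q_1)/1.35$ rule is available as
  `method = "iqr135"` for cross-checks.
* **Ratio with 95% CI** -- the log-scale Wald statistic $t =
  \log(\mathrm{ratio}) \cdot 2 z_{0.975} / (\log CI_u - \log CI_l)$,
  treated as a $t$ on $\nu = n_1 + n_2 - 2$ degrees of freedom. This is
  the standard stand-in when the original analysis was a Cox or
  proportional-odds model; the magnitude matches the original Wald $z$,
  and referring it to a $t$ distribution is slightly conservative. Every
  result row records that this approximation was applied.

A `direction` flag states which way benefit points for each outcome (a
recovery-rate ratio above 1 is good; a mortality hazard ratio above 1 is
bad); it is configuration, never inferred, and only affects the reported
sign of $t$, not the two-sided Bayes factor.

### Numerics

The alternative marginal likelihood is integrated over $\delta$ after the
exact substitution $\delta = r \tan u$, which maps the real line to
$(-\pi/2, \pi/2)$ and absorbs the Cauchy density, so no tail truncation is
ever needed. The panel containing the likelihood peak (at $u =
\arctan\{t/(r\sqrt{N})\}$) is integrated first to relative tolerance
$10^{-6}$; the remaining panels are then allowed an absolute tolerance
scaled to the peak panel's value, which stops the adaptive rule from
chasing roundoff in regions where the integrand has underflowed to zero.
The Bayes factor is assembled in log space (`log_bf01` is always finite;
`bf01` itself may under- or overflow doubles for decisive data, and
categorization happens on the log scale), and quadrature failure raises an
explicit error rather than falling back silently. The same quantity is
independently available through the $g$-mixture representation (an
inverse-gamma$(1/2, r^2/2)$ integral using only elementary functions); the
test suite holds the two routes, plus a dense-trapezoid oracle, to within
$10^{-4}$ relative error of each other.

## The 2x2 table path

Binary outcomes (deaths, responders) per arm are modeled with fixed row
margins -- the arm sizes, fixed by randomization -- and per-arm event
rates $\theta_1, \theta_2$. Under $H_1$ the rates are independent with
$\mathrm{Beta}(a, a)$ priors; under $H_0$ there is a single common rate.
Two variants differ only in the null prior:

* `indep_binomial` (default): common rate $\theta \sim \mathrm{Beta}(a, a)$,
  i.e. uniform for the default $a = 1$ on every rate parameter under both
  hypotheses.
* `gd_indep_multinomial`: the Gunel & Dickey (1974) independent-multinomial
  form, whose null prior is the Dirichlet row-sum marginal
  $\mathrm{Beta}(2a, 2a)$; this is what standard contingency-table Bayes
  factor software computes for this sampling plan, and it is provided for
  cross-checks against such software.

Both are exact closed forms in log-Beta functions, total over all valid
tables (zero cells and all-event cells included, no continuity
corrections), and stable for arm sizes in the thousands. The uniform
`indep_binomial` model is the pipeline default: it is the natural "all
rates uniform a priori" description of a two-arm mortality comparison, and
it is the variant under which the packaged remdesivir trial values
reproduce their reference analyses (see `analysis/01_reanalyze_trials.R`);
the difference between variants is itself a mild form of prior sensitivity
and can be displayed by switching `contingency_variant`.

## Evidence ladder

`categorize()` maps `BF01` to the conventional verbal ladder: beyond 3 (or
below 1/3) moderate, beyond 10 (or below 1/10) strong, in between
ambiguous. Exact threshold values are assigned outward on the null side
(`3` counts as moderate pro-null, `10` as strong pro-null) and inward on
the alternative side (`1/3` and `1/10` count as the weaker and stronger
pro-alternative categories respectively); thresholds are measure-zero and
never arise from the pipeline's floating-point output, so the convention
is cosmetic but documented.

## Prior sensitivity

`sensitivity_curve()` recomputes a Bayes factor over a grid of prior
settings -- Cauchy scales $\{\sqrt{2}/4, \sqrt{2}/2, 1, \sqrt{2}\}$ by
default, spanning narrow through ultrawide defaults -- and
`robustness_summary()` reports whether one evidence category holds across
the whole grid. For count tables the analogous exercise varies the Beta
concentration $a$ over the same grid. In the packaged remdesivir
reanalysis, nine of fifteen comparisons are category-stable; the unstable
ones all sit close to a ladder threshold, which the curve makes visible
rather than hiding behind a single number.

## What the synthetic generator emulates

The generator produces exactly the three data structures the reanalysis
assumes, with known truth and a per-replicate seed stream (replicate $k$
of root seed $s$ is reproducible in isolation):

* `simulate_continuous_trial()`: Normal$(\delta, 1)$ vs Normal$(0, 1)$ --
  the literal JZS data model -- emitting both mean/SD and quartile
  summaries of the same samples, so the exact and the
  quartile-reconstructed paths can be compared replicate by replicate.
* `simulate_binary_trial()`: binomial event counts at stated per-arm
  probabilities.
* `simulate_recovery_trial()`: log-normal recovery times (right-skewed,
  as recovery times are; a two-parameter family whose median is directly
  settable) with administrative right-censoring. Censored observations
  contribute the censoring day to the observed quartiles and are counted;
  if an observed quartile lands on the censoring day the generator errors,
  because the underlying quartile is then not identified. Default
  scenario parameters (medians 11 vs 15 days, $\sigma_{\log} = 0.6$,
  censoring at day 28, 500/arm) mimic the size and contrast of a large
  recovery-time trial.

What the generator does *not* emulate: ordinal clinical-status scales
(those enter real reanalyses only through published ratio summaries),
informative censoring or dropout, covariate adjustment, and adaptive
designs. Passing calibration tests therefore show that the chain is
correct *for its stated data model*, not that the Wald-CI reconstruction
of a Cox model is exact -- that approximation is checked only for
magnitude plausibility, as discussed below.

`evidence_calibration()` runs the full chain on replicated scenarios and
tabulates evidence-category frequencies. At the study conditions used
throughout the package (500 replicates; null with 1000/arm; $\delta = 1$
with 100/arm), a true null accumulates `BF01 > 3` in about 94% of
replicates and a large effect reaches `BF01 < 1/3` in essentially all --
the asymmetry (nulls accumulate evidence slowly, effects fast) is the
expected behavior of Bayes factors, not a bug.

## Known limitations

* **Ratio-CI reconstruction is approximate.** The reconstructed $t$ equals
  the Wald $z$ implied by the published interval; the original survival or
  ordinal model statistic can differ by several percent (different
  information matrices, profile vs Wald intervals, rounding of the
  published CI to two digits). Near a ladder threshold this can move the
  verbal category. The packaged remdesivir config documents, per record,
  which values were reconstructed this way.
* **Quartile summaries lose efficiency.** The IQR-based SD estimate is
  noisier than the sample SD. At 100/arm under a true null -- where
  `BF01` concentrates near the moderate threshold 3 -- the quartile-based
  and moment-based paths agree in evidence category in only about 88% of
  replicates (recomputed by `scripts/acceptance.R` as
  `quartile_vs_moments_category_agreement_pct`); agreement is essentially
  complete for decisive effects. Conclusions that depend on a category
  reached from quartile summaries alone deserve the sensitivity treatment.
* **Transcription uncertainty.** Two fixture entries (ACTT-1 day-15 death
  counts, Solidarity no-ventilation subgroup counts) are flagged as
  approximate transcriptions in their `notes`; their Bayes factors should
  be read at category rather than digit precision.
* **No meta-analysis.** Outcomes differ across trials, so the pipeline
  deliberately analyzes every comparison separately and never pools.

## Problem sizes

The test suite and the acceptance script use 500-replicate simulations,
oracle grids of $\sim 100$ configurations for the quadrature cross-check,
and exhaustive table enumeration up to $30 \times 30$ margins -- sizes at
which every Monte-Carlo bound in the tests has comfortable slack relative
to its binomial standard error, chosen once as part of the package's
design.

```{r example}
# the full packaged reanalysis
res <- run_reanalysis(remdesivir_trials())
res[, c("trial_id", "outcome", "subgroup", "bf01_display", "category")]
```
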