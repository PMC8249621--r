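---
title: "Methods: actigraphy sleep scoring, circadian metrics and group modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actigraphy sleep scoring, circadian metrics and group modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
library(dplyr)
```

`actisleep` implements an end-to-end analysis of 1-minute epoch wrist
actigraphy for field cohorts observed in two socio-ecological locations
(a village and a forest camp): sleep/wake scoring and per-night sleep
quotas, non-parametric circadian rhythm analysis (NPCRA), two-group
contrasts with default-prior Bayes factors, random-intercept mixed models
with AIC-weighted shrinkage averaging, and functional linear modelling
(FLM) of 24-h activity curves. Because raw device exports from such
studies are rarely shareable, the package ships a synthetic cohort
generator that emulates the study design, so every stage is testable
end-to-end with no external data.

## Sleep/wake scoring

Commercial actigraphy software scores sleep with proprietary algorithms
that are described only as thresholding a weighted activity signal. We
therefore use a documented classifier of the Cole–Kripke family: minute
$i$ is scored *sleep* when

$$\sum_{j=-h}^{h} w_j \, c_{i+j} \le \tau,$$

with a centred, symmetric weight vector $w$ (default length 7, peaked at
the centre: 0.04, 0.08, 0.2, 1, 0.2, 0.08, 0.04) and threshold $\tau$
(default 100 count units). Both are exposed in `scoring_config()` so
users can calibrate against their device; series edges are padded by
replication, and off-wrist minutes are always scored wake. The default
threshold is in the regime where quiescent minutes (tens of counts) score
sleep and mobile minutes (hundreds to thousands of counts) score wake for
typical wrist devices; it is deliberately not tuned to any one device.

Analysis days run **noon to noon**, so nocturnal sleep bouts are never
split by a day boundary; a night is dated by its starting noon. Within a
day, the main rest period opens at the first run of at least
`rest_block_min` (default 10) consecutive sleep-scored minutes whose
start falls in the night window (default 18:00–06:00), and closes at the
end of the last such rest run before the following noon. Requiring a
10-minute run avoids single-epoch artifacts at the rest edges; the night
window constrains only where the main bout may *start*, so late waking is
not truncated. Days with no qualifying run (or under 18 h of data) are
excluded and logged.

Quotas per night: TIB is the onset-to-end span of the main period; TST
the sleep-scored minutes within it; WASO the wake-scored minutes within
it; efficiency $= 100\cdot\mathrm{TST}/\mathrm{TIB}$; TTST adds
sleep-scored nap minutes (naps are sleep runs of at least 20 minutes
outside the main period); and the nap quota is TTST $-$ TST. With TIB
defined as the onset-to-end span, TST $+$ WASO $=$ TIB exactly, and
efficiency is bounded in $[0, 100]$. The fragmentation index is the sum
of two percentages over the main period: mobile (wake-scored) minutes as
a share of inferred sleep time, plus immobile bouts of length $\le 1$
minute as a share of all immobile bouts. We equate the mobile/immobile
dichotomy with the wake/sleep classification — a single movement
threshold — and document that choice rather than introducing a second,
unobservable threshold.

## Non-parametric circadian rhythm analysis

For recordings with at least seven complete noon-to-noon days (shorter
recordings are excluded, matching the usual NPCRA inclusion rule), the
package computes on hourly bins ($p = 24$, $N = 24D$):

$$\mathrm{IS} = \frac{N \sum_{h=1}^{p} (\bar x_h - \bar x)^2}
                     {p \sum_{i=1}^{N} (x_i - \bar x)^2}, \qquad
  \mathrm{IV} = \frac{N \sum_{i=2}^{N} (x_i - x_{i-1})^2}
                     {(N-1) \sum_{i=1}^{N} (x_i - \bar x)^2}.$$

Hourly binning is the classical convention for these statistics;
epoch-resolution versions are available via `npcra_metrics(bin =
"epoch")`. Useful calibration points (all verified in the test suite):
a perfectly repeated day gives IS $= 1$; i.i.d. noise gives
$E[\mathrm{IS}] \approx 1/D$ and $E[\mathrm{IV}] \approx 2$; an
hourly-sampled 24-h sinusoid gives IV $= 2(1 - \cos(2\pi/24)) \approx
0.068$. Published IV values from vendor software can sit well below the
nominal 0–2 range, which is consistent with a different internal
binning/normalization; absolute IV values are therefore comparable within
one convention only.

M10 and L5 are the mean counts over the most active 10 consecutive hours
and least active 5 consecutive hours of the *average day* (minute-of-day
means). Both are searched at 1-minute resolution over all 1440 circular
start positions — field studies report M10 onsets to the minute — with
ties broken toward the earliest clock time after midnight. Relative
amplitude is $(\mathrm{M10} - \mathrm{L5})/(\mathrm{M10} + \mathrm{L5})$.

## Two-group contrasts

Nights are first aggregated to one value per subject per location
("controlling for repeated nights" read as subject-level aggregation, the
simplest defensible interpretation); clock-time variables are aggregated
circularly on the 24-h circle, since onsets such as 23:30 and 00:30 must
average to midnight. Magnitude variables are contrasted with a
Jeffreys–Zellner–Siow (JZS) two-sample Bayes factor — a Cauchy prior of
scale $\sqrt{2}/2$ on the standardized effect, evaluated by adaptive
quadrature of the one-dimensional $g$ integral — with the Raftery bands
(1–3 weak, 3–10 modest, 10–30 strong, $>30$ very strong; $\mathrm{BF}
\le 1$ null-favoured; band edges assigned to the lower band, a
convention the band table leaves open). Clock times are compared with
Welch t-tests after circular unwrapping about the joint circular mean,
and timing variability with a two-sided variance F-test. The test suite
checks the Bayes factor against an independent fine-grid quadrature over
the effect size using the noncentral-t likelihood.

## Mixed models and shrinkage averaging

Each sleep quota is modelled as a linear mixed model with a subject
random intercept; fixed terms are rainfall, temperature, humidity, moon
phase, age, gender, location and the gender-by-location interaction
(moon phase is retained as a controlled environmental term even where a
display formula omits it; a flag can drop it). Continuous predictors are
z-scored and factors coded 0/1 against the references *woman* and
*village*. Outcomes are z-scored by default so reported coefficients are
standardized; raw-scale fits are available via
`standardize_outcome = FALSE`.

All marginality-respecting subsets of the fixed terms (an interaction
only with both main effects; 160 candidates for the full 8-term model)
are fitted by **maximum likelihood** — REML likelihoods are not
comparable across fixed-effect structures — and models within
$\Delta\mathrm{AIC} < 10$ of the best are averaged with Akaike weights.
(The window is interpreted as $\Delta$AIC relative to the best model, the
standard usage; an absolute AIC cutoff would be meaningless.) The
shrinkage (full) average substitutes zero for a coefficient in models
that exclude its term, pulling weakly supported terms toward zero; the
unconditional standard error combines within-model variance with
between-model spread, and 95% CIs are $\hat\beta \pm 1.96\,\mathrm{SE}$.

## Functional linear modelling

Per-participant 24-h activity curves are minute-of-day means over at
least two complete days — the inclusion rule we adopt for the ambiguous
"two consecutive days" convention — projected onto a periodic Fourier
basis with $K = 9$ harmonics (19 basis functions, resolving features at
roughly the 80-minute scale; $K$ is configurable). Groups are compared
with the pointwise one-way F statistic over the 1440-minute grid, and
significance is calibrated by permuting participants' group labels as
whole curves (500 permutations, $\alpha = 0.05$ by default): the critical
curve is the empirical $1-\alpha$ quantile of the permuted F at each
minute. Permutation at the participant level respects within-participant
dependence across minutes; a pointwise (not maximum-statistic) critical
value is used deliberately, so under the null about $\alpha$ of minutes
exceed it — the test suite verifies calibration within $[0.03, 0.07]$
averaged over replicates.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analysis assumes:

* **Roster.** 39 village participants (20 men) and 23 forest
  participants (10 men), 11 of whom appear in both locations (7 men),
  giving 51 unique subjects whose random intercepts span locations; ages
  drawn around mean 36 (SD 13.75), truncated to 17–72.
* **Nights.** 3–8 nights per participant. Uniform draws are nudged by
  seeded unit steps to meet the design's per-location totals (226 village
  and 136 forest nights); the totals are part of the emulated design, not
  a free parameter, and can be disabled with `nights_total = NULL`.
* **Sleep structure.** Each gender-by-location cell carries its own
  onset/end clock means and SDs, target TST and nap duration, taken from
  the emulated study's summary tables (e.g. forest women onset ≈ 20:47
  with ≈ 1:24 SD and TST 6.53 h vs forest men 21:17, ≈ 1:57 and 5.65 h —
  forest men's timing variability is severalfold women's). Nightly WASO
  is the drawn window span minus the drawn TST, placed as interior wake
  bouts between sleep segments of at least 10 minutes; this construction
  makes the configured cell TST offsets (e.g. +0.88 h for forest women
  over forest men) hold in the *scored* output by construction, which a
  WASO-rate parameterization cannot guarantee jointly with the timing
  table.
* **Counts.** Daytime counts are negative-binomial around a nonnegative
  two-harmonic diurnal template with gender/location multipliers —
  activity counts are bursty and Gaussian noise would produce negatives —
  sleep minutes are low-rate Poisson, and wake bouts ramp up and down
  (low outer minutes, fully mobile interior), as arousals do. With the
  default templates the generated rhythms sit in the strongly rhythmic
  regime (relative amplitude above 0.8).
* **Naps** fall in a 12:00–15:00 window with daily probability 0.7 and
  cell-specific mean durations: midday rest is where a mid-morning
  activity decline would place it; nap timing is otherwise unconstrained
  by the emulated design.
* **Weather.** Nightly temperature and humidity are sampled at 21:00,
  00:00, 03:00 and 06:00 around per-night bases (means in the 21–25 °C
  band, humidity mean 84%), rainfall is zero-inflated gamma, and moon
  illumination follows a sinusoidal 29.5-day cycle.

What the generator does **not** emulate: off-wrist artifacts, infant
co-sleeping dynamics, seasonal drift, weather–sleep coupling (weather
covariates are generated independently of the sleep draws, so mixed-model
weather terms are null under the defaults), and the exact empirical count
distributions of unreleased raw data. Passing tests therefore demonstrate
that the pipeline recovers structure *of the kind the design specifies*,
not that it reproduces any particular dataset.

## Numerical choices and degenerate inputs

* Interior recording gaps of at most 10 minutes are imputed as zero-count
  off-wrist epochs; longer gaps are a loud error — silently fabricating
  sleep is worse than failing.
* IS/IV are undefined (0/0) for constant series and raise; the
  fragmentation index raises when there are no immobile bouts; relative
  amplitude raises at M10 $=$ L5 $= 0$; circular means raise for exactly
  balanced (antipodal) time sets.
* The JZS integral is evaluated with `integrate()` at relative tolerance
  1e-9, with the null density factored into the integrand to avoid
  underflow at large $|t|$.
* Zero-variance predictors and constant outcomes raise before model
  fitting; non-converged candidates are dropped from the averaging set.
* M10/L5 ties (constant profiles) resolve to the earliest clock time.

## Problem sizes used by the test suite

The suite generates all fixtures in code. The heavier checks use: a full
study-sized cohort (62 series, 362 nights) for night bookkeeping; two
63-participant, 8-night cells (about 500 nights each) for the scored-TST
calibration of the generator; 1000 replicates for the IS/IV noise
expectations; 100 random profiles against the brute-force M10/L5 scan;
50 null replicates at 500 permutations on a 10-minute grid for FLM
type-I calibration; and 100 replicates of a 60-subject, 6-night design
for mixed-model recovery and null CI calibration. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances.

## A short worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(seed = 1))
quotas <- cohort_quotas(coh)
summarize_quotas(quotas, "location")

compare_groups(quotas, "efficiency_pct", "location")
fit <- sleep_lmm_average(quotas, "tst_h")
tidy(fit)

flm <- flm_compare(coh, "gender", seed = 1)
autoplot(flm)
```

## Known limitations

The scorer is a single-threshold family and will not reproduce any
proprietary algorithm bit-for-bit; absolute quota levels depend on the
threshold calibration, while contrasts between groups scored identically
are far more stable. NPCRA absolute values (especially IV) are
convention-dependent. Published Bayes factors and mixed-model
coefficients from field datasets cannot be reproduced without the raw
data; the package's claims are therefore identities, closed forms and
calibration properties, all of which the test suite computes.
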