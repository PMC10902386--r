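---
title: "Forecasting depression severity from smartphone behavior: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting depression severity from smartphone behavior: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

moodcast turns raw smartphone sensor streams into daily behavioral features
and predicts a person's future depression severity — a CAT-DI score on a
0–100 scale — weeks ahead of the last completed assessment. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic cohort emulates (and does not), and the design
choices made where the procedure was genuinely open.

## The prediction problem

Depression severity is assessed sparsely — every one or two weeks at best —
while phone sensors observe behavior continuously. The package treats the
assessments as noisy readings of a continuously varying latent severity
trait, interpolates that trait to daily resolution, and regresses it on
daily behavioral features. Three model families are compared:

* **idiographic** — one elastic net per person, allowing each person their
  own feature–mood slopes;
* **nomothetic** — a single pooled elastic net, assuming common slopes;
* **nomothetic\*** — the pooled model plus one unpenalized indicator per
  person, i.e. person-specific intercepts with shared slopes, analogous to a
  random-intercept model.

A **baseline** model with only an intercept and the study day quantifies
how much of the apparent accuracy is mere trend-following; feature-based
models are reported as log2 fold changes in error against it.

## Sensor features

**Mobility.** GPS fixes are filtered to stationary observations (average
speed since the previous fix < 0.7 m/s, about half walking pace, haversine
distance on a 6,371 km sphere). Each day's stationary fixes are clustered
by complete-linkage hierarchical clustering on great-circle distance, cut
at an 800 m diameter so every venue has a consistent radius; venues
occupied less than 15 minutes in the day are discarded as artifacts
(traffic stops, repeated walk-throughs). Positions are linearly
interpolated every 3 minutes between observed fixes, each grid point
assigned to the nearest venue within 400 m of its centroid or labeled
transit. The home venue is wherever the person dwells most between
midnight and 08:00, with ties going to the venue visited earlier. From the
trace we compute time at home, number of venues, location entropy
$-\sum_i p_i \ln p_i$ over dwell shares, and normalized entropy
$/\ln(n)$ (defined as 0 for a single venue), over the full day and the
night/day/evening 8-hour windows, plus whole-day aggregates (transit
share, distance traveled, venue span, first/last movement, venue
transitions, maximal distance from home) — 23 activity features. The
windows follow the local clock and are half-open, so an event exactly at
08:00 belongs to the day window; daylight-saving days simply have 23 or 25
clock hours.

**Sleep.** The longest phone-off period in a 20:00–12:00 search window is
the assumed uninterrupted sleep; its endpoints proxy bedtime and waketime,
encoded as signed minutes from midnight so 23:30 (−30) and 00:30 (+30)
average sensibly. Only off-periods closed by an observed on/unlock event,
starting before 04:00 and reaching past midnight, are sleep candidates —
otherwise a night bordering a day of missing sensor data would yield
absurd 12-hour "sleeps" truncated at the window edge. Night usage counts
closed screen-on intervals between midnight and 08:00 (a proxy for
interrupted sleep), and the circadian interaction nadir is the minimum of
a circular Gaussian kernel density (24 h period, 1 h bandwidth, 1-minute
grid, earliest minute on ties) over the day's interactions; it needs at
least three interactions. Thirteen sleep features in total. The count of
sleep, activity, social, and device-usage features follows the study
design this package emulates, but the full inventories are not published;
the concrete feature lists here are the package's own documented
reconstruction.

**Social and device usage.** Call counts by direction, call minutes, the
percentage of connected calls that were outgoing, unique contacts, and the
proportion of unique contacts among outgoing calls and texts — 18
features, with SMS-derived ones only emitted for Android devices, which
are the only platform exposing SMS logs. Unlock count and total screen-on
minutes form the two device-usage features. A day with no communication
events is a genuine zero, not missing data, provided the screen sensor
shows the phone was alive that day.

## Feature expansion and missing data

Because current mood may reflect behavior over days to weeks, each daily
feature is expanded with trailing means and variances over windows of 3,
7, 14, and 30 strictly prior days (the current day never enters its own
windows), requiring at least ⌈w/2⌉ observed days per window — a coverage
rule the package adopts to bound window noise. Contrasts between window
pairs (the single-day value against each window, and shorter against
longer windows: difference and ratio with a 10⁻⁶ guard) capture "slept
less last night than is typical this week". With the full feature set this
yields on the order of 1,400 columns per person.

Per person, features missing on more than 90% of *training* days are
dropped (strictly greater; decided on the training split only). The rest
are completed by iterative soft-thresholded SVD matrix completion: fill
missing cells from the current low-rank estimate, take the SVD,
soft-threshold the singular values by λ, reconstruct, repeat until the
relative Frobenius change falls below 10⁻⁵ (cap 500 iterations). The
penalized objective ½‖P<sub>obs</sub>(X−Z)‖² + λ‖Z‖<sub>*</sub> is
non-increasing across iterations. λ defaults to one fifth of the top
singular value of the mean-filled training matrix; the rank cap is
min(50, dims). Columns are internally centered and scaled inside the
imputer so heterogeneous units share one threshold — observed entries are
restored exactly on output. New (test) rows are completed by a ridge
projection of their observed entries onto the fitted right factors, so
the training-fitted model applies to both splits. Finally all features are
z-scored with training-split means and standard deviations;
zero-variance training columns are dropped. Imputation is fitted
separately per person — behavioral covariance structure is individual.

## Latent trait interpolation

Four interpolation methods generate daily severity targets between the
first and last assessment (no extrapolation): last observation carried
forward (LOCF); cubic smoothing splines with 4 effective degrees of
freedom (one per severity category: normal <35, mild 35–65, moderate
65–75, severe 75–100); with degrees of freedom equal to the number of
severity categories the person actually visited in training (clamped to
2–4); and with degrees of freedom chosen by leave-one-out cross-validation
(grid 2…min(10, n−2), ties to the smaller df). Splines are penalized
cubic smoothing splines whose smoothing parameter is solved so the
effective degrees of freedom — the trace of the smoother matrix — match
the request to within 10⁻³; values are clipped to [0, 100]. A
no-interpolation mode keeps only assessment days. When a person's training
series is too short for the requested spline, the fit falls back to LOCF.

Leakage is the central design concern: training responses come from a
spline fitted on training-split assessments only, while evaluation targets
come from the full-series fit. Test-set accuracy is computed at test
assessment days by default (for LOCF the target then equals the raw
observed score); scoring every test day against the full-series spline is
available as an option, since either reading of the evaluation protocol is
defensible.

## Models

The response y is the daily latent trait on training days; predictors are
the standardized features plus the study day (standardized with the same
training statistics; the baseline's unpenalized fit is scale-invariant).
The "logistic" family models y/100 as a fractional response under binomial
deviance — predictions 100·σ(η) can never leave the severity scale — and
its coefficients are reported as odds ratios. The linear family uses the
identity link; its out-of-range predictions are set to missing and excluded
from evaluation rather than clipped. The elastic-net mixing parameter is
fixed at α = 0.5 and λ is selected by 10-fold cross-validation minimizing
deviance. Folds are contiguous time blocks within each person's training
span by default — random folds would let serial correlation leak
information between folds — but seeded random folds are available to
reproduce the plain procedure. The modified-nomothetic person indicators
are excluded from the penalty so intercepts are not shrunk toward the
pooled mean. The train/test split takes the first ⌊0.7 n⌋ assessments
(at least 4, so a spline is identifiable) as training; people with fewer
than 5 assessments, under 60 sensor days inside their assessment span, or
no training-score variation are excluded.

## Evaluation

MAPE uses 100·mean(|o−p| / max(o, 1)); the ε = 1 floor guards genuine
zero scores. Pearson's R between observed and predicted is tested
one-sided (ρ > 0), R² is reported in percent together with a likelihood
ratio test of the observed~predicted regression against intercept-only,
and individual-level records (people with ≥5 valid test pairs) are
corrected across people by Benjamini–Hochberg at 5%: a person is
"significantly predicted" when R > 0 and q < 0.05. Horizon curves bin
pooled pairs by ⌈days-ahead/7⌉ and attach seeded bootstrap CIs (1,000
resamples; bins under 10 pairs suppressed). Idiographic top-predictor
reports keep features whose odds ratio leaves [0.95, 1.05], ranked by
|log OR|.

One calibration caveat deserves emphasis. Spline-interpolated evaluation
targets are serially smoothed, so neighboring test-day targets are far
from independent; a per-person correlation test against them is
anti-conservative, and on a null cohort (couplings all zero, flat latent
structure) it declares the majority of subjects "significant" even though
the features carry no information. Against raw observed scores — the LOCF
target — the same procedure is well calibrated (essentially no null
subjects pass BH at 5%). The package therefore runs its null-calibration
check against raw-score targets, and spline-target accuracy figures
should be read as descriptive smoothness-adjusted fits, not as
independently tested significance.

The variance partition of assessment scores fits a linear mixed model by
maximum likelihood with categorical study parameters (person, season,
wave, sex, year) as random intercepts and continuous ones (study day, age,
a pandemic indicator) as fixed effects; each fixed effect's variance is
the post-hoc var(Xβ̂) and every component is reported as a fraction of
the total. Confidence intervals use a nonparametric bootstrap over
subjects — simpler than a parametric bootstrap and adequate for
fraction-scale uncertainty.

## The synthetic cohort

Real study data of this kind are restricted, so the package ships a
generator whose ground truth makes every stage testable. Latent mood is a
subject intercept ~ N(55, 15²) truncated to [5, 95] — drawn so
between-person differences dominate, as observed in longitudinal severity
data, and so all severity categories occur across a cohort — plus a linear
drift (total-drift sd 10 points), a seasonal sinusoid (half-normal
amplitude, sd 8 points, period 60–120 days — swings large enough to cross
severity categories, as real trajectories do), and AR(1) noise (φ = 0.9,
stationary sd = `noise_sd`). Mood couples to behavior through per-person
loadings on five driver features (time at home via the logit of the home
dwell share, venue count via a log Poisson rate, sleep duration in
minutes, call count and screen sessions via log rates); the
`effect_heterogeneity` knob spreads loadings across people in units of
each feature's reference magnitude, so 0 gives a homogeneous cohort and 2
a strongly heterogeneous one with frequent sign flips. Raw events are then
sampled conditional on the daily expected values: GPS dwells at venues
placed ≥2 km apart with 15 m position noise and irregular fix cadence
(median gap under 5 minutes), screen sessions with a pre-bed phone check
and occasional brief night interruptions, Poisson calls and texts.
Assessments follow a weekly or biweekly schedule from day 1, with
geometric dropout and observation noise, clipped to [0, 100]. Sensor-day
missingness is missing-at-random — the one mechanism the emulated study
design considers plausible — at a configurable daily rate.

For planted-effect recovery analyses, `simulate_recovery_cohort()` builds
a purpose-made cohort: one nonzero loading per subject (cycled over the
five drivers, random sign, strong magnitude) and latent trajectories
rebuilt with a fixed 15-point sinusoid plus mild AR(1) noise, so every
subject's severity genuinely varies — a coupling whose driver never moves
cannot be recovered by any method. Because a driver mechanically moves a
whole family of extracted features (a higher home-dwell share shortens
away-venue dwells and thereby lowers venue counts, entropy and span;
longer sleep delays the first morning interaction and inflates overnight
time at home), recovery is scored against the generator's own
`driven_features()` map — the elastic net may legitimately surface any
member of a mechanically coupled family, with the sign the mechanics
imply. Exact duplicate design columns are removed before fitting for the
same reason: identical columns split elastic-net weight arbitrarily.
Recovery is evaluated under the LOCF latent trait, the least-smoothed
target, where the features' contribution is not pre-absorbed by the
spline's trend.

What the generator does *not* emulate: platform differences beyond an
SMS-availability flag, location semantics (work versus home labels),
non-MAR missingness, measurement reactivity, or the study's exact
demographics and attrition percentages. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers structure it is
pointed at — not that real phones yield signals this clean.

## Problem sizes and numerical choices

The package's own verification runs use desk-scale cohorts chosen to keep
a complete check of all stages comfortably reproducible on a laptop: an
end-to-end cohort of 40 subjects × 200 days with strong heterogeneous
couplings, a null-calibration cohort of 200 subjects × 120 days with all
couplings zero (screen/communication features only, no window expansion),
and a variance-partition cohort of 200 subjects × 20 biweekly
assessments. Determinism is enforced throughout: per-stream generator
seeds derive from the cohort seed, clustering labels order by first-visit
time, LOOCV ties break toward smaller df, home-venue ties toward the
earlier first visit, nadir ties toward the earlier minute, and
cross-validation folds are deterministic time blocks unless random folds
are requested. Degenerate inputs have defined behavior: empty days give
missing features, a never-off phone gives sleep 0 with missing bed/wake
times, zero connected calls give a missing outgoing percentage, 0/0
normalized entropy is 0, and fully missing feature rows impute to column
means.

## Known limitations

Idiographic models are fitted independently per person and waste no
strength across people; they assume a (log-)linear feature–severity
relationship. The latent trait is a smoothing device, not a validated
state-space model; accuracy against spline targets overstates accuracy
against raw scores, which is why the LOCF and no-interpolation variants
are always available. The feature inventory is a reconstruction, and the
soft-impute completion assumes low-rank behavioral structure with MAR
missingness.
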