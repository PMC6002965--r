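---
title: "cgmhypo: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgmhypo: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmhypo)
```

cgmhypo analyses the relationship between endogenous insulin secretion
(random plasma C-peptide, pmol/l) and hypoglycaemia in insulin-treated
diabetes. Because no patient-level data can ship with the package, a
calibrated stochastic simulator stands in for the two study cohorts: a
CGM study contrasting severe insulin deficiency (rCP < 200 pmol/l)
against preserved secretion (> 600 pmol/l) at 17 subjects per arm, and a
questionnaire study splitting 256 insulin-treated subjects with type 2
diabetes at 200 pmol/l (35 low, 221 high). This vignette documents the
models, the tunable parameters, the calibration and the numerical
conventions, and what the simulation-based tests do and do not show.

## The trace model

A subject's interstitial glucose is simulated on a uniform grid (default
5 min, the common professional-CGM sampling interval) as

$$ g(t) = \max\{\mu_i + A\cos(2\pi (h(t) - \phi)/24) + X(t),\; F\}
          \;\;\oplus\;\; \text{excursions}, $$

* $\mu_i \sim N(\mu_{\text{group}}, \sigma_b^2)$ — per-subject baseline,
  group means 10.2 / 9.9 mmol/l (the two cohorts are matched on mean
  glucose), between-subject SD $\sigma_b = 1.5$ mmol/l chosen so that
  simulated group means of per-subject means vary on the scale of the
  study's reported confidence intervals.
* $A = 1.2$ mmol/l, acrophase $\phi = 8$ h — a modest circadian component
  peaking in the morning (dawn-phenomenon-like). The studies report no
  circadian decomposition; this magnitude is a plausibility choice and
  contributes $A^2/2 = 0.72$ (mmol/l)² to the stationary variance.
* $X(t)$ — Ornstein–Uhlenbeck noise, reversion $\theta = 0.5$/h (2-h
  correlation time) and stationary SD `ou_sd`, discretised *exactly* as an
  AR(1): $X_{k+1} = e^{-\theta\Delta}X_k + \sigma\sqrt{1 - e^{-2\theta\Delta}}\,\varepsilon_k$,
  so the stationary SD equals the configured parameter at any sampling
  interval (an Euler scheme would bias it).
* $F = 4.2$ mmol/l — a counter-regulatory floor applied to the background
  process only. Sustained spontaneous drift below ~4 mmol/l is
  physiologically resisted by counter-regulation; in the model, *all*
  time below the 4.0 mmol/l detection threshold is therefore carried by
  discrete insulin-driven excursions. This is a deliberate
  identifiability choice: the excursion process's rate, depth and
  duration parameters are then exactly what the episode detector should
  recover, and the high group's "deep hypoglycaemia only at night"
  behaviour is an exact property of the generator rather than a
  probabilistic one.
* Output is clamped to 1.1–33.3 mmol/l (the 20–600 mg/dl sensor
  reporting range).

## The excursion process

Hypoglycaemic excursions arrive as a Poisson process (defaults 5.5 and
2.1 events/subject/week for the low and high group). Each event replaces
a span of the background with a cosine-tapered dip: half-cosine ramps of
20 min blend down to, and back up from, a drawn nadir, separated by a
hold at the nadir. The below-4.0-mmol/l duration is drawn lognormal with
mean 114.5 min (low) / 106 min (high) — the reported weekly duration
divided by the reported weekly rate — CV 0.5, truncated to 25–420 min so
every event is detectable under the 20-min rule; the hold length is
solved from the ramp geometry so the time at or below 4.0 mmol/l
approximates the drawn duration. A single half-cosine profile over the
whole span was rejected: at typical depths it spends only ~25% of its
span below threshold, so matching the reported durations would require
spans several hours long, saturating the trace and making night-only
placement impossible.

Nadirs are a two-component uniform mixture: *deep* (1.9–3.0 mmol/l) with
probability 1.8/5.5 (low) or 0.4/2.1 (high) — the ratio of the reported
sub-3.0 rate to the total rate — otherwise *shallow* (3.05–3.9). The
deep range's lower end makes roughly a quarter of deep events reach the
severe 2.2 mmol/l threshold, consistent with the reported (low) severe
rates. In the high group deep events are confined to a 00:00–08:00 night
window (`p_night_deep = 1`); in the low group placement is uniform,
which already reproduces the reported predominance of daytime deep
episodes (expected day share 2/3). Events are kept disjoint with > 20 min
separation (bounded re-draws) so injected events map one-to-one onto
detected episodes; a configuration requesting > 50% trace occupancy is
rejected.

## Calibration

The total per-subject SD of glucose mixes the OU component, the
circadian term, the floor censoring and the excursion dips, so the OU SD
that achieves a target total SD has no closed form. `calibrate_ou_sd()`
bisects the OU SD on a pilot simulation of the full model (60–80
subjects × 14 days) until the mean per-subject SD hits the group target
(4.15 / 3.01 mmol/l). The shipped defaults, `ou_sd = 4.16` (low) and
`2.88` (high), are the output of that one calibration pass and are not
adjusted further. With excursions disabled the closed form
$\sqrt{\sigma_{OU}^2 + A^2/2}$ is recovered directly, which the test
suite uses as an oracle.

## Quality control conventions

Windows are consecutive 24-h blocks anchored at the session start, not
calendar-aligned: sessions begin mid-day and the inclusion criteria are
stated per 24 h without an anchor. A trailing partial window is
discarded unevaluated, so the default 4.25-day recording yields at most
4.0 retained days. SMBG readings pair to the nearest grid sample within
±5 min (one sampling interval); a reading equidistant between two
samples takes the earlier one. MAD% uses the SMBG as the denominator
(the capillary reading is the reference, as in MARD-style sensor
accuracy summaries). The correlation and MAD criteria are strict
inequalities as stated (*r* > 0.77, MAD% < 28): values exactly at the
boundary fail. An undefined correlation (fewer than two pairs or zero
variance on either side) fails the criterion rather than passing
vacuously. QC is monotone by construction — tightening any threshold can
only excise more windows — and excised windows contribute to no
downstream quantity: metrics and episodes are computed on the retained
segments only, and an episode can never span an excised window.

## Metric and episode conventions

Metrics pool each subject's retained samples into one series (matching
batch GV calculators, which operate on the full series) rather than
averaging per-window values. MAGE collapses plateaus and monotone runs
to turning points, keeps excursions whose amplitude exceeds 1 SD of the
whole series, and averages them in the direction of the first qualifying
excursion; series whose boundary half-excursions qualify contribute
them, and a constant series returns `NA` (undefined). LBGI converts with
1 mmol/l = 18.016 mg/dl and uses every sample, not episode-gated values.

Episode detection is a state machine over consecutive samples: each
sample at or below threshold contributes one sampling interval of
below-time; below-runs separated by an above-threshold gap of ≤ 20 min
(including exactly 20) merge, because completion requires *more than*
20 min above threshold; merged-gap time is excluded from the reported
duration, which counts time at/below threshold only. Episodes qualify at
≥ 20 min of below-time and are assigned wholly to day (08:00–00:00) or
night (00:00–08:00) by start time — boundary instants 08:00 → day,
00:00 → night — since splitting an episode across periods would
double-count it. Rates scale counts by 168 / retained hours.

## Statistics

Paired *t* tests operate on within-pair differences (df = n − 1,
two-sided). The χ² test is Pearson's without continuity correction (a
Yates switch exists as a sensitivity option). Raw Poisson rates get
exact Garwood intervals, $[\chi^2_{0.025, 2k}/2,\ \chi^2_{0.975, 2k+2}/2]/T$,
with lower bound 0 at $k = 0$. The two-group rate comparison is a *z*
test on the log rate ratio with $SE = \sqrt{1/k_1 + 1/k_2}$ — the log
scale is chosen (over a difference-of-rates *z*) because the ratio is
the reported effect measure; zero events in either group yield an
explicit unbounded-CI flag, never a silent infinity. Adjusted models are
IRLS-fitted GLMs (logistic → OR, Poisson log-link with exposure offset →
rate ratio, Gaussian/ANCOVA → adjusted mean difference) with Wald 95%
CIs for the group coefficient; non-convergence and suspected separation
are reported in the result's `note` field. All tests are two-sided at
α = 0.05 with no multiplicity correction, matching the study analysis.

## Questionnaire model

Clarke scoring sums seven binary awareness items (≥ 4 = reduced
awareness; nothing is imputed — a missing item is an error). The
modified instrument's exact item wording is not reproduced here, so
which survey questions feed the seven items is left to the data-entry
configuration. Question 5/6 categories recode to episodes/month as
0, 2, 4, 10, 18, 25; "none" is forced to 0. The simulator draws true
monthly counts from Poisson with group means 3.5/1.4 (low) and 1.8/0.69
(high) and reports the category whose recoded value is nearest the
count, ties to the lower category — so the recoding is the
quantisation's fixed point and group rate ratios survive the round trip
approximately, not exactly.

## Problem sizes used by the shipped checks

The replicate-study aggregation (`replicate_cgm_study()`) uses 20
replicate seeds of the default 17 + 17 cohort at 4.25 recording days
(≈ 25 million samples in total, about 12 s); oracle-equivalence
property tests use 1000 random traces of ≤ 200 samples for the episode
machine and ≤ 100 samples for MAGE; regression-recovery checks use
n = 2000 per fit across 10–20 replicates. These sizes give Monte-Carlo
errors well inside the asserted tolerances while keeping the whole
suite fast.

## What passing tests do and do not show

The generator reproduces the *summary structure* of real CGM cohorts —
matched means, distinct within-subject SDs, excursion rates, depths,
durations and their day/night pattern, SMBG calibration noise — and the
pipeline demonstrably recovers those generating parameters. It does not
emulate meal or insulin-dose dynamics, sensor drift, compression
artefacts, or non-stationary behaviour across days; the plateaus it
produces at the counter-regulatory floor are a stylisation. Passing the
round-trip tests therefore validates the analysis code and the
calibration, not the physiological realism of any individual trace, and
agreement with the published group summaries on simulated cohorts is a
consistency check, not a re-analysis of the original patients.

## Known limitations

* MAGE has several circulating operationalisations; plateau handling and
  endpoint excursions follow the turning-point convention described
  above, and other implementations may differ at the boundaries.
* The exact composition of the modified Clarke questionnaire is
  configuration, not code.
* Adjusted odds/rate ratios from the original questionnaire cohort
  cannot be reproduced without the patient-level covariate joint
  distribution; the package verifies its regression machinery by
  parameter recovery on simulated data instead.
* Timestamps assume a single local timezone without DST transitions
  (sessions are ≤ 7 days).
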