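# cgmhypo

Pipeline for relating endogenous insulin secretion — measured as random
non-fasting plasma C-peptide (rCP) — to hypoglycaemia risk in
insulin-treated diabetes. Patients with severe insulin deficiency
(rCP < 200 pmol/l) show markedly higher glucose variability and more
frequent, longer hypoglycaemia than patients with preserved secretion,
despite similar mean glucose; this package implements every computational
stage needed to demonstrate that contrast from continuous glucose
monitoring (CGM) and questionnaire data:

* **CGM quality control** — per-24-hour windows kept only with ≥3 paired
  self-monitored blood glucose (SMBG) calibrations, no missing samples,
  SMBG–sensor Pearson *r* > 0.77 and MAD% < 28, where
  MAD% = mean(|SMBG − sensor| / SMBG) × 100; subjects with < 24 h retained
  are excluded.
* **Glycaemic variability metrics** — mean, SD (n − 1), MAGE (mean
  amplitude of excursions exceeding 1 SD, counted in the direction of the
  first qualifying excursion) and LBGI, the low blood glucose index
  `LBGI = mean(10 f(g)² · 1[f(g) < 0])` with
  `f(g) = 1.509((ln g_mg/dl)^1.084 − 5.381)`.
* **Hypoglycaemia episode detection** — an episode is ≥ 20 min at or below
  a threshold (4.0, 3.0 or 2.2 mmol/l) and is only complete once glucose
  has been above the threshold for > 20 min; episodes are assigned to day
  (08:00–00:00) or night (00:00–08:00) by start time and converted to
  exposure-normalised rates (episodes/person/week) and durations
  (min/person/week).
* **Clarke questionnaire** — seven 0/1 awareness items summed (score ≥ 4 =
  reduced awareness) and question 5/6 frequency categories recoded to
  episodes/month: none→0, 1–3/month→2, 1/week→4, 2–3/week→10, 4–5/week→18,
  almost daily→25.
* **Group statistics** — paired *t* tests, Pearson χ², exact (Garwood)
  Poisson rate CIs from chi-square quantiles, log-scale rate-ratio *z*
  tests, and covariate-adjusted logistic/Poisson/ANCOVA models via IRLS.
* **Calibrated cohort simulator** — per-subject traces built as baseline +
  circadian sinusoid + exact-AR(1) Ornstein–Uhlenbeck noise above a
  counter-regulatory floor, with hypoglycaemic excursions injected as a
  Poisson process with group-specific rates, depths and durations, plus
  SMBG readings and questionnaire responses. Every generator output is a
  pure function of (config, seed).

## Worked example

```r
library(cgmhypo)
run <- run_pipeline(cgm_study_config(seed = 1), mode = "cgm-study")
print(run)
```

```
== cgmhypo report (mode cgm-study, seed 1) ==

-- CGM arm --
subjects analysed: low n=17, high n=17
mean_glucose           low 9.72 (8.86, 10.57) | high 9.29 (8.54, 10.04)
sd_glucose             low 3.90 (3.67, 4.13) | high 2.79 (2.65, 2.93)
mage                   low 5.63 (5.26, 6.00) | high 3.89 (3.68, 4.09)
lbgi                   low 1.67 (1.18, 2.17) | high 0.72 (0.43, 1.01)
prop_any_episode @4.0  low 1.00 | high 0.65
rate_per_week @4.0     low 5.66 (3.93, 7.39) | high 1.96 (1.06, 2.85)
duration_min_per_week @4.0 low 622.28 (394.62, 849.94) | high 188.38 (92.26, 284.51)
```

One simulated 17-vs-17 cohort: the low-C-peptide group has similar mean
glucose but higher SD, MAGE and LBGI, all 17 low-C-peptide subjects have
at least one episode at ≤ 4.0 mmol/l, and their episode rate and weekly
hypoglycaemia duration are roughly 3× those of the high-C-peptide group.
`run$cgm$comparisons` holds the paired *t*, χ² and rate-ratio contrasts
with CIs and p-values; `run_pipeline(..., out_dir = "out")` writes the
per-stage CSV tables and a JSON/text report. User-supplied CSVs (schemas
in `?write_cohort_csv`) can replace the simulator via the `inputs`
argument.

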