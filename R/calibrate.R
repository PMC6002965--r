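#' Calibrate the OU stationary SD against a total-SD target
#'
#' Injected excursions, the circadian component and the
#' counter-regulatory floor all contribute to (or censor) the total
#' per-subject SD of glucose, so the Ornstein-Uhlenbeck stationary SD
#' that yields a desired total SD cannot be written down in closed form.
#' This routine runs a bisection on a pilot simulation of one group:
#' at each candidate `ou_sd` it simulates `n_subjects` traces with the
#' group's full model (heterogeneous baselines, excursions, floor,
#' clamping) and compares the mean per-subject SD with the target.
#'
#' The shipped defaults in [cgm_study_config()] were produced by this
#' routine; it is exported so the calibration is reproducible and so
#' users can re-calibrate after changing any other trace parameter.
#'
#' @param cfg a `generator_config`.
#' @param group group label to calibrate.
#' @param target_sd desired mean per-subject SD of glucose (mmol/l).
#' @param n_subjects pilot size per bisection step.
#' @param days pilot recording length in days.
#' @param lower,upper bisection bracket for `ou_sd`.
#' @param iter bisection iterations.
#' @param seed pilot seed.
#' @return the calibrated `ou_sd` (numeric scalar).
#' @export
calibrate_ou_sd <- function(cfg, group, target_sd, n_subjects = 60,
                            days = 14, lower = 0.5, upper = 8,
                            iter = 12, seed = 1L) {
  pilot <- cfg
  pilot$recording_days <- days
  mean_sd_at <- function(s) {
    pilot$groups[[group]]$trace$ou_sd <- s
    sds <- vapply(seq_len(n_subjects), function(i) {
      subj <- list(subject_id = sprintf("P%03d", i), group = group)
      tr <- generate_trace(subj, pilot, derive_seed(seed, i, 5))
      stats::sd(tr$glucose)
    }, numeric(1))
    mean(sds)
  }
  lo <- lower
  hi <- upper
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mean_sd_at(mid) < target_sd) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
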