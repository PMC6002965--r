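# Independent oracles and fixture builders used across the suite.

# Explicit-scan episode oracle: enumerate maximal below-threshold runs by
# index walking, merge runs separated by short above-gaps, keep episodes
# with enough below-threshold time.  Deliberately written as plain loops,
# not via rle(), so it is an independent check on the detector.
oracle_episodes <- function(glucose, threshold, dt,
                            min_dur = 20, max_gap = 20) {
  below <- glucose <= threshold
  n <- length(below)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- i:j
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  eps <- list()
  for (r in runs) {
    if (length(eps) &&
        (min(r) - max(eps[[length(eps)]]) - 1) * dt <= max_gap) {
      eps[[length(eps)]] <- c(eps[[length(eps)]], r)
    } else {
      eps[[length(eps) + 1]] <- r
    }
  }
  eps <- Filter(function(e) length(e) * dt >= min_dur, eps)
  data.frame(start_index = vapply(eps, min, numeric(1)),
             duration_min = vapply(eps, length, numeric(1)) * dt,
             nadir = vapply(eps, function(e) min(glucose[e]), numeric(1)))
}

# Neighbour-comparison MAGE oracle: local extrema found by direct sign
# products after plateau collapse; qualifying amplitudes averaged in the
# direction of the first qualifying excursion.
oracle_mage <- function(glucose) {
  s <- stats::sd(glucose)
  v <- glucose[c(TRUE, diff(glucose) != 0)]
  if (length(v) < 2 || s == 0) return(NA_real_)
  ext <- v[1]
  if (length(v) > 2) {
    for (i in 2:(length(v) - 1)) {
      if ((v[i] - v[i - 1]) * (v[i + 1] - v[i]) < 0) ext <- c(ext, v[i])
    }
  }
  ext <- c(ext, v[length(v)])
  amps <- diff(ext)
  qual <- abs(amps) > s
  if (!any(qual)) return(NA_real_)
  dir <- sign(amps[which(qual)[1]])
  mean(abs(amps[qual & sign(amps) == dir]))
}

# A flat trace with explicit values, anchored at a chosen clock time.
make_trace <- function(glucose, start = "2023-03-06 00:00:00",
                       interval_min = 5, subject_id = "T001") {
  glucose_trace(subject_id, as.POSIXct(start, tz = "UTC"),
                interval_min, glucose)
}

# Random short glucose series for property tests: a lazy random walk
# with occasional plateaus, clipped to a physiologic range.
random_walk_trace <- function(n, start_value = 6) {
  steps <- sample(c(-1.5, -0.5, 0, 0, 0.5, 1.5), n - 1, replace = TRUE)
  pmin(pmax(cumsum(c(start_value, steps)), 1.2), 25)
}

# Noise-free single-group config: constant background at `baseline`,
# no OU noise, no circadian, no subject heterogeneity.
noise_free_config <- function(baseline = 10, rate_per_week = 5.5,
                              n = 4, days = 4, seed = 11L) {
  g <- group_config(
    label = "low", n = n, cpeptide_range = c(5, 190),
    trace = list(baseline_mean = baseline, between_subject_sd = 0,
                 circadian_amp = 0, acrophase_hour = 8,
                 ou_theta_per_hr = 0.5, ou_sd = 0, floor = 4.2),
    excursions = list(rate_per_week = rate_per_week, dur_mean_min = 114.5,
                      dur_cv = 0.5, dur_range = c(25, 420),
                      p_deep = 0.33, deep_nadir = c(1.9, 3.0),
                      shallow_nadir = c(3.05, 3.9),
                      p_night_deep = 0, ramp_min = 20),
    questionnaire = list(q5_mean = 3.5, q6_mean = 1.4, q3_mean = 0.5,
                         q4_mean = 0.25, item_p = 0.3))
  generator_config(groups = list(low = g), recording_days = days,
                   seed = seed)
}
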