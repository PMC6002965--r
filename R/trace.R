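#' Construct a glucose trace
#'
#' A `glucose_trace` is one subject's uniformly sampled interstitial
#' glucose series with clock-time anchoring.  Missing samples are
#' explicit `NA`s on the grid, never omitted rows.
#'
#' @param subject_id subject identifier.
#' @param start session start, `POSIXct` (UTC).
#' @param interval_min sampling interval in minutes.
#' @param glucose numeric vector of glucose samples in mmol/l (`NA` for
#'   missing).
#' @return an object of class `glucose_trace`.
#' @export
glucose_trace <- function(subject_id, start, interval_min, glucose) {
  stopifnot(interval_min > 0)
  g <- as.numeric(glucose)
  if (any(g[!is.na(g)] <= 0))
    stop("input error: glucose samples must be > 0 mmol/l")
  structure(list(subject_id = subject_id, start = as_utc(start),
                 interval_min = interval_min, glucose = g),
            class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> subject %s: %d samples @ %g min from %s (%.2f days)\n",
              x$subject_id, length(x$glucose), x$interval_min,
              format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
              length(x$glucose) * x$interval_min / 1440))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$glucose)

#' Sample timestamps of a trace
#' @param trace a `glucose_trace`.
#' @return `POSIXct` vector, one element per sample.
#' @export
trace_times <- function(trace) {
  trace$start + (seq_along(trace$glucose) - 1) * trace$interval_min * 60
}

# Minutes past midnight (local clock) for each sample.
trace_clock_min <- function(trace) {
  start_min <- as.numeric(format(trace$start, "%H", tz = "UTC")) * 60 +
    as.numeric(format(trace$start, "%M", tz = "UTC"))
  (start_min + (seq_along(trace$glucose) - 1) * trace$interval_min) %% 1440
}

#' Simulate one subject's background CGM trace and inject excursions
#'
#' The background process is baseline mean + circadian sinusoid +
#' stationary Ornstein-Uhlenbeck noise, discretised exactly as an AR(1)
#' (so the stationary SD is exactly the configured `ou_sd`), then clipped
#' at the counter-regulatory floor.  Hypoglycaemic excursions are
#' injected by [inject_excursions()] and the result is clamped to the
#' sensor reporting range.  The per-subject baseline mean is drawn as
#' `baseline_mean + N(0, between_subject_sd^2)` from the same stream, so
#' the whole trace is a pure function of `(subject, cfg, seed)`.
#'
#' The injected ground-truth event log is attached as
#' `attr(trace, "events")`.
#'
#' @param subject one row of a subject table (needs `subject_id` and
#'   `group`), or a list with those fields.
#' @param cfg a `generator_config`.
#' @param seed integer stream seed (>= 0).
#' @return a `glucose_trace` with an `events` attribute.
#' @export
generate_trace <- function(subject, cfg, seed) {
  validate_config(cfg)
  if (seed < 0) stop("input error: seed must be >= 0")
  grp <- cfg$groups[[as.character(subject$group)]]
  if (is.null(grp))
    stop("config error: subject group '", subject$group,
         "' absent from config")
  tr <- grp$trace
  dt_min <- cfg$interval_min
  n <- round(cfg$recording_days * 24 * 60 / dt_min)

  set.seed(as.integer(seed))
  mu_i <- tr$baseline_mean + stats::rnorm(1, 0, tr$between_subject_sd)
  mu_i <- max(mu_i, tr$floor + 2)   # keep the background physiologic

  hour_of_day <- (as.numeric(format(cfg$session_start, "%H", tz = "UTC")) +
                    as.numeric(format(cfg$session_start, "%M", tz = "UTC")) / 60 +
                    (seq_len(n) - 1) * dt_min / 60) %% 24
  circ <- tr$circadian_amp * cos(2 * pi * (hour_of_day - tr$acrophase_hour) / 24)

  # exact AR(1) discretisation of the OU process
  rho <- exp(-tr$ou_theta_per_hr * dt_min / 60)
  x <- numeric(n)
  eps <- stats::rnorm(n)
  x[1] <- tr$ou_sd * eps[1]
  innov_sd <- tr$ou_sd * sqrt(1 - rho^2)
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + innov_sd * eps[i]

  g <- pmax(mu_i + circ + x, tr$floor)
  trace <- glucose_trace(subject$subject_id, cfg$session_start, dt_min, g)
  trace <- inject_excursions(trace, grp$excursions,
                             derive_seed(seed, 1, 9), clamp = cfg$clamp)
  trace$glucose <- pmin(pmax(trace$glucose, cfg$clamp[1]), cfg$clamp[2])
  trace
}

# Fraction of a half-cosine ramp (depth 0 -> 1 over its length) spent at
# blend weight >= c.
ramp_frac_below <- function(c) {
  c <- pmin(pmax(c, 0), 1)
  1 - acos(pmin(pmax(1 - 2 * c, -1), 1)) / pi
}

#' Inject hypoglycaemic excursions into a background trace
#'
#' The number of events is Poisson with mean `rate_per_week` times the
#' recording length in weeks.  Each event replaces a contiguous span with
#' a cosine-tapered dip: half-cosine ramps of `ramp_min` minutes blend
#' the background down to, and back up from, a drawn nadir, with a hold
#' at the nadir sized so that the time spent at or below the 4.0 mmol/l
#' detection threshold approximates the drawn below-threshold duration.
#' Durations are lognormal with the configured mean and CV, truncated to
#' `dur_range`.  Nadirs come from a two-component uniform mixture (deep,
#' i.e. <= 3.0 mmol/l, with probability `p_deep`, else shallow); with
#' probability `p_night_deep` a deep event is placed entirely inside a
#' 00:00-08:00 night window.  Events are kept disjoint with a > 20 min
#' separation (bounded re-draws; an event that cannot be placed is
#' dropped and counted in `attr(,"events_dropped")`).
#'
#' @param trace a gap-free `glucose_trace`.
#' @param params excursion parameter list (see [group_config()]).
#' @param seed integer stream seed.
#' @param clamp sensor range used for the saturation check.
#' @return the modified trace; `attr(, "events")` holds the ground-truth
#'   event log (one row per injected event: `start_offset_min`,
#'   `span_min`, `duration_min`, `nadir`, `deep`, `night_restricted`,
#'   `start_time`).
#' @export
inject_excursions <- function(trace, params, seed, clamp = c(1.1, 33.3)) {
  if (anyNA(trace$glucose))
    stop("input error: inject_excursions requires a gap-free trace")
  dt <- trace$interval_min
  n <- length(trace$glucose)
  total_min <- n * dt
  weeks <- total_min / 10080

  set.seed(as.integer(seed))
  empty_log <- data.frame(start_offset_min = numeric(0), span_min = numeric(0),
                          duration_min = numeric(0), nadir = numeric(0),
                          deep = logical(0), night_restricted = logical(0))
  if (params$rate_per_week == 0) {
    attr(trace, "events") <- empty_log
    attr(trace, "events_dropped") <- 0L
    return(trace)
  }

  expected_span <- params$dur_mean_min + 2 * params$ramp_min
  if (params$rate_per_week * weeks * expected_span > 0.5 * total_min)
    stop("config error: requested excursions would saturate > 50% of the trace")

  n_events <- stats::rpois(1, params$rate_per_week * weeks)
  sdlog <- sqrt(log(1 + params$dur_cv^2))
  meanlog <- log(params$dur_mean_min) - sdlog^2 / 2
  clock0 <- trace_clock_min(trace)[1]

  # candidate night windows [start, end) in trace-offset minutes
  night_starts <- ((0 - clock0) %% 1440) + 1440 * (0:ceiling(total_min / 1440 + 1))
  nights <- cbind(night_starts, night_starts + 480)
  nights <- nights[nights[, 1] >= 0 & nights[, 2] <= total_min, , drop = FALSE]

  occupied <- matrix(numeric(0), ncol = 2)  # [start, end) minutes, with buffer
  log_rows <- vector("list", n_events)
  dropped <- 0L
  g <- trace$glucose
  for (ev in seq_len(n_events)) {
    deep <- stats::runif(1) < params$p_deep
    rng <- if (deep) params$deep_nadir else params$shallow_nadir
    nadir <- stats::runif(1, rng[1], rng[2])
    night <- deep && stats::runif(1) < params$p_night_deep
    placed <- FALSE
    for (try in 1:200) {
      d <- stats::rlnorm(1, meanlog, sdlog)
      if (d < params$dur_range[1] || d > params$dur_range[2]) next
      # hold length so that time at/below 4.0 mmol/l ~ d
      probe <- if (night && nrow(nights)) {
        nights[sample.int(nrow(nights), 1), ]
      } else c(0, total_min)
      # the trace's average background level sets the ramp geometry
      bg <- mean(g)
      cc <- (bg - 4.0) / (bg - nadir)
      below_ramps <- 2 * params$ramp_min * ramp_frac_below(cc)
      hold <- max(d - below_ramps, dt)
      span <- hold + 2 * params$ramp_min
      lo <- probe[1]
      hi <- probe[2] - span
      if (hi <= lo) next
      t0 <- stats::runif(1, lo, hi)
      t1 <- t0 + span
      if (nrow(occupied) &&
          any(t0 < occupied[, 2] & t1 > occupied[, 1])) next
      idx <- which((seq_len(n) - 1) * dt >= t0 & (seq_len(n) - 1) * dt < t1)
      if (!length(idx)) next
      occupied <- rbind(occupied, c(t0 - 20, t1 + 20))
      tt <- (idx - 1) * dt - t0
      w <- ifelse(tt < params$ramp_min,
                  (1 - cos(pi * tt / params$ramp_min)) / 2,
                  ifelse(tt > span - params$ramp_min,
                         (1 - cos(pi * (span - tt) / params$ramp_min)) / 2,
                         1))
      g[idx] <- g[idx] * (1 - w) + nadir * w
      log_rows[[ev]] <- data.frame(start_offset_min = t0, span_min = span,
                                   duration_min = d, nadir = nadir,
                                   deep = deep, night_restricted = night)
      placed <- TRUE
      break
    }
    if (!placed) dropped <- dropped + 1L
  }
  trace$glucose <- pmin(pmax(g, clamp[1]), clamp[2])
  events <- do.call(rbind, log_rows)
  if (is.null(events)) events <- empty_log
  events <- events[order(events$start_offset_min), , drop = FALSE]
  if (nrow(events))
    events$start_time <- trace$start + events$start_offset_min * 60
  attr(trace, "events") <- events
  attr(trace, "events_dropped") <- dropped
  trace
}

#' Simulate SMBG calibration readings for a trace
#'
#' Capillary readings are taken `per_day` times a day at jittered
#' mealtime-like clock hours; each reading equals the sensor value at the
#' nearest grid sample times multiplicative lognormal noise with the
#' configured CV (mean 1).
#'
#' @param trace a `glucose_trace`.
#' @param cfg a `generator_config`.
#' @param seed integer stream seed.
#' @return data frame with columns `subject_id`, `time` (`POSIXct`),
#'   `glucose` (mmol/l).
#' @export
generate_smbg <- function(trace, cfg, seed) {
  if (!length(trace$glucose)) stop("input error: empty trace")
  if (cfg$smbg$per_day < 0) stop("config error: readings/day must be >= 0")
  set.seed(as.integer(seed))
  per_day <- cfg$smbg$per_day
  out <- data.frame(subject_id = character(0), time = as.POSIXct(character(0)),
                    glucose = numeric(0))
  if (per_day == 0) return(out)

  dt <- trace$interval_min
  total_min <- length(trace$glucose) * dt
  clock0 <- trace_clock_min(trace)[1]
  times_hour <- rep_len(cfg$smbg$times_hour, per_day)
  n_days <- ceiling(total_min / 1440) + 1
  nominal <- as.vector(outer(times_hour * 60, (0:(n_days - 1)) * 1440, "+")) -
    clock0
  nominal <- nominal + stats::rnorm(length(nominal), 0, cfg$smbg$jitter_sd_min)
  keep <- nominal >= 0 & nominal < total_min
  offsets <- sort(nominal[keep])
  idx <- pmin(length(trace$glucose), pmax(1, round(offsets / dt) + 1))
  sdlog <- sqrt(log(1 + cfg$smbg$cv^2))
  noise <- if (sdlog == 0) rep(1, length(idx)) else
    stats::rlnorm(length(idx), -sdlog^2 / 2, sdlog)
  sens <- trace$glucose[idx]
  ok <- !is.na(sens)
  data.frame(subject_id = trace$subject_id,
             time = trace$start + offsets[ok] * 60,
             glucose = sens[ok] * noise[ok])
}
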