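#' Detect hypoglycaemia episodes at a glucose threshold
#'
#' A candidate run is a maximal stretch of consecutive samples at or
#' below the threshold.  Runs separated by an above-threshold gap of
#' 20 min or less belong to the same episode -- an episode is only
#' complete once readings have been above the threshold for more than
#' 20 min.  An episode qualifies when its summed below-threshold time is
#' at least 20 min, each sample contributing one sampling interval.
#' Episode duration is the below-threshold time only (merged-gap time is
#' excluded).  Episodes never span QC-excised windows: detection runs
#' independently within each contiguous retained segment.
#'
#' Each episode is assigned wholly to the day (08:00-00:00) or night
#' (00:00-08:00) period containing its start; an episode starting at
#' exactly 08:00 is day, at exactly 00:00 night.
#'
#' @param segments a `glucose_trace` or list of contiguous retained
#'   segments on a common uniform grid.
#' @param threshold glucose threshold in mmol/l (> 0), e.g. 4.0, 3.0,
#'   2.2.
#' @param min_duration_min minimum qualifying below-threshold time
#'   (default 20 min).
#' @param max_gap_min longest above-threshold gap that does not complete
#'   an episode (default 20 min; a gap of exactly 20 min merges).
#' @return data frame, one row per episode: `subject_id`, `threshold`,
#'   `start`, `end`, `duration_min`, `nadir`, `period`.
#' @export
detect_episodes <- function(segments, threshold, min_duration_min = 20,
                            max_gap_min = 20) {
  if (threshold <= 0) stop("input error: threshold must be > 0")
  if (inherits(segments, "glucose_trace")) segments <- list(segments)
  out <- lapply(segments, detect_episodes_segment, threshold = threshold,
                min_duration_min = min_duration_min,
                max_gap_min = max_gap_min)
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), threshold = numeric(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = numeric(0), nadir = numeric(0),
                      period = character(0))
  out
}

detect_episodes_segment <- function(trace, threshold, min_duration_min,
                                    max_gap_min) {
  g <- trace$glucose
  if (anyNA(g))
    stop("input error: non-uniform grid (missing samples) inside a segment")
  dt <- trace$interval_min
  below <- g <= threshold
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge below-runs separated by an above gap <= max_gap_min
  ep_id <- integer(nrow(runs))
  cur <- 1L
  ep_id[1] <- cur
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap_min <- (runs$start[i] - runs$end[i - 1] - 1) * dt
      if (gap_min > max_gap_min) cur <- cur + 1L
      ep_id[i] <- cur
    }
  }
  rows <- lapply(split(runs, ep_id), function(rr) {
    below_samples <- sum(rr$end - rr$start + 1)
    dur <- below_samples * dt
    if (dur < min_duration_min) return(NULL)
    i0 <- min(rr$start)
    i1 <- max(rr$end)
    idx <- unlist(Map(seq, rr$start, rr$end), use.names = FALSE)
    start_time <- trace$start + (i0 - 1) * dt * 60
    clock_min <- (as.numeric(format(trace$start, "%H", tz = "UTC")) * 60 +
                    as.numeric(format(trace$start, "%M", tz = "UTC")) +
                    (i0 - 1) * dt) %% 1440
    data.frame(subject_id = trace$subject_id, threshold = threshold,
               start = start_time,
               end = trace$start + i1 * dt * 60,
               duration_min = dur, nadir = min(g[idx]),
               period = if (clock_min < 480) "night" else "day")
  })
  do.call(rbind, rows)
}

#' Day/night episode counts and rates
#'
#' Episodes are assigned wholly to the period containing their start
#' (day 08:00-00:00, night 00:00-08:00); the assignment is made at
#' detection time and summarised here.
#'
#' @param episodes an episode data frame from [detect_episodes()].
#' @param exposure_hours retained monitoring time in hours (> 0); if
#'   supplied, per-week rates are added.
#' @return data frame with one row per period: `period`, `count` and,
#'   when exposure is given, `rate_per_week`.
#' @export
day_night_split <- function(episodes, exposure_hours = NULL) {
  counts <- vapply(c("day", "night"),
                   function(p) sum(episodes$period == p), numeric(1))
  out <- data.frame(period = c("day", "night"), count = as.integer(counts))
  if (!is.null(exposure_hours)) {
    if (exposure_hours <= 0) stop("input error: exposure must be > 0")
    out$rate_per_week <- out$count * 168 / exposure_hours
  }
  out
}

#' Exposure-normalised hypoglycaemia summary for one subject
#'
#' Counts, episode rates and total below-threshold durations per person
#' per week at each threshold, with day/night sub-rates.  Rates scale
#' the observed counts by `168 / exposure hours`.
#'
#' @param episodes episode data frame for one subject (any mix of
#'   thresholds).
#' @param exposure_hours retained monitoring hours (> 0).
#' @param subject_id subject identifier.
#' @param thresholds thresholds to summarise (default 4.0, 3.0,
#'   2.2 mmol/l).
#' @return data frame, one row per threshold: `subject_id`, `threshold`,
#'   `count`, `rate_per_week`, `duration_min_per_week`, `day_rate`,
#'   `night_rate`, `exposure_weeks`.
#' @export
summarize_hypo <- function(episodes, exposure_hours, subject_id = NULL,
                           thresholds = c(4, 3, 2.2)) {
  if (exposure_hours <= 0) stop("input error: exposure must be > 0")
  if (is.null(subject_id))
    subject_id <- if (nrow(episodes)) episodes$subject_id[1] else NA_character_
  scale <- 168 / exposure_hours
  rows <- lapply(thresholds, function(th) {
    ep <- episodes[episodes$threshold == th, , drop = FALSE]
    dn <- day_night_split(ep)
    data.frame(subject_id = subject_id, threshold = th,
               count = nrow(ep),
               rate_per_week = nrow(ep) * scale,
               duration_min_per_week = sum(ep$duration_min) * scale,
               day_rate = dn$count[dn$period == "day"] * scale,
               night_rate = dn$count[dn$period == "night"] * scale,
               exposure_weeks = exposure_hours / 168)
  })
  do.call(rbind, rows)
}
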