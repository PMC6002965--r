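#' Pair SMBG calibration readings with sensor samples
#'
#' Each capillary reading is matched to the nearest-in-time sensor sample
#' within a tolerance (default +/- 5 min, one sampling interval).  A
#' reading equidistant between two samples pairs with the earlier one.
#' Readings with no sample inside the tolerance, or whose matched sample
#' is missing, are dropped with a warning.
#'
#' @param trace a `glucose_trace`.
#' @param readings data frame with `subject_id`, `time`, `glucose`.
#' @param tol_min pairing tolerance in minutes.
#' @return data frame with one row per retained pair: `time`, `smbg`,
#'   `sensor`, `sample_index`, `offset_min` (reading time as minutes from
#'   session start).
#' @export
pair_smbg_to_sensor <- function(trace, readings, tol_min = 5) {
  if (nrow(readings) && !all(readings$subject_id == trace$subject_id))
    stop("input error: SMBG subject id does not match trace")
  empty <- data.frame(time = as.POSIXct(character(0), tz = "UTC"),
                      smbg = numeric(0), sensor = numeric(0),
                      sample_index = integer(0), offset_min = numeric(0))
  if (!nrow(readings)) return(empty)
  dt <- trace$interval_min
  off <- as.numeric(difftime(readings$time, trace$start, units = "mins"))
  # nearest grid sample, ties (x.5) broken towards the earlier sample
  frac <- off / dt
  idx <- ifelse(frac - floor(frac) == 0.5, floor(frac), round(frac)) + 1
  ok <- idx >= 1 & idx <= length(trace$glucose) &
    abs(off - (idx - 1) * dt) <= tol_min
  ok[ok] <- !is.na(trace$glucose[idx[ok]])
  if (any(!ok))
    warning(sum(!ok), " SMBG reading(s) dropped (no sensor sample within ",
            tol_min, " min)")
  data.frame(time = readings$time[ok], smbg = readings$glucose[ok],
             sensor = trace$glucose[idx[ok]],
             sample_index = as.integer(idx[ok]), offset_min = off[ok])
}

#' Evaluate one 24-h window against the CGM inclusion criteria
#'
#' A window passes only if all four criteria hold: at least
#' `min_calibrations` paired SMBG calibrations; no missing sensor
#' samples; Pearson correlation between paired SMBG and sensor readings
#' strictly greater than `r_min`; and MAD% strictly below `mad_max`,
#' where MAD% is the mean over pairs of `|smbg - sensor| / smbg x 100`.
#' A correlation that is undefined (fewer than 2 pairs, or zero variance
#' on either side) fails the correlation criterion.
#'
#' @param glucose sensor samples of the window (`NA` = missing).
#' @param pairs data frame of calibration pairs falling in the window
#'   (columns `smbg`, `sensor`).
#' @param min_calibrations,r_min,mad_max the three numeric criteria.
#' @return one-row data frame with the measured values, per-criterion
#'   pass flags and overall `pass`.
#' @export
evaluate_window <- function(glucose, pairs, min_calibrations = 3,
                            r_min = 0.77, mad_max = 28) {
  if (!length(glucose)) stop("input error: empty window")
  n_cal <- nrow(pairs)
  completeness <- mean(!is.na(glucose))
  r <- if (n_cal >= 2 && stats::sd(pairs$smbg) > 0 &&
           stats::sd(pairs$sensor) > 0)
    stats::cor(pairs$smbg, pairs$sensor) else NA_real_
  mad_pct <- if (n_cal >= 1)
    mean(abs(pairs$smbg - pairs$sensor) / pairs$smbg) * 100 else NA_real_
  pass_cal <- n_cal >= min_calibrations
  pass_complete <- completeness == 1
  pass_r <- !is.na(r) && r > r_min
  pass_mad <- !is.na(mad_pct) && mad_pct < mad_max
  data.frame(n_calibrations = n_cal, completeness = completeness,
             r = r, mad_pct = mad_pct,
             pass_calibrations = pass_cal, pass_complete = pass_complete,
             pass_r = pass_r, pass_mad = pass_mad,
             pass = pass_cal && pass_complete && pass_r && pass_mad)
}

#' Apply per-24-hour quality control to a CGM trace
#'
#' The trace is partitioned into consecutive 24-h windows anchored at the
#' session start; a trailing partial window is discarded without
#' evaluation.  Each full window is evaluated with [evaluate_window()]
#' against the calibration readings falling inside it; failing windows
#' are excised.  A subject with less than 24 h of retained data is
#' flagged excluded.
#'
#' @param trace a `glucose_trace`.
#' @param readings SMBG data frame for the same subject.
#' @param min_calibrations,r_min,mad_max criteria passed to
#'   [evaluate_window()].
#' @param tol_min SMBG pairing tolerance in minutes.
#' @return list with `report` (one row per window, class `qc_report`),
#'   `segments` (list of contiguous retained `glucose_trace` pieces),
#'   `retained_hours`, `retained_days`, `excluded`.
#' @export
apply_qc <- function(trace, readings, min_calibrations = 3, r_min = 0.77,
                     mad_max = 28, tol_min = 5) {
  dt <- trace$interval_min
  spw <- 1440 / dt                      # samples per 24-h window
  n_win <- floor(length(trace$glucose) / spw)
  pairs <- pair_smbg_to_sensor(trace, readings, tol_min = tol_min)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    lo_min <- (w - 1) * 1440
    sel <- pairs$offset_min >= lo_min & pairs$offset_min < lo_min + 1440
    g <- trace$glucose[((w - 1) * spw + 1):(w * spw)]
    row <- evaluate_window(g, pairs[sel, , drop = FALSE],
                           min_calibrations = min_calibrations,
                           r_min = r_min, mad_max = mad_max)
    rows[[w]] <- cbind(data.frame(subject_id = trace$subject_id,
                                  window = w,
                                  window_start = trace$start + lo_min * 60),
                       row)
  }
  report <- if (n_win) do.call(rbind, rows) else
    data.frame(subject_id = character(0), window = integer(0), pass = logical(0))
  class(report) <- c("qc_report", class(report))
  passing <- if (n_win) which(report$pass) else integer(0)
  segments <- list()
  if (length(passing)) {
    runs <- split(passing, cumsum(c(1, diff(passing) != 1)))
    segments <- lapply(runs, function(ws) {
      i0 <- (min(ws) - 1) * spw + 1
      i1 <- max(ws) * spw
      glucose_trace(trace$subject_id, trace$start + (i0 - 1) * dt * 60,
                    dt, trace$glucose[i0:i1])
    })
    names(segments) <- NULL
  }
  retained_hours <- length(passing) * 24
  list(report = report, segments = segments,
       retained_hours = retained_hours,
       retained_days = retained_hours / 24,
       excluded = retained_hours < 24)
}
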