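#' Build a cohort generator configuration
#'
#' A `generator_config` bundles everything the synthetic-cohort simulator
#' needs: the sampling grid, the per-group glucose-trace model (baseline
#' mean, circadian modulation, Ornstein-Uhlenbeck noise, counter-regulatory
#' floor), the hypoglycaemic excursion process, the SMBG calibration
#' schedule and the questionnaire response model.
#'
#' Trace values are interstitial glucose in mmol/l throughout; rates are
#' episodes per subject per week; durations are minutes.
#'
#' @param groups named list of group definitions, each built with
#'   [group_config()].
#' @param interval_min CGM sampling interval in minutes; must divide 60.
#' @param recording_days length of each subject's recording session in days
#'   (may be fractional; a trailing partial 24-h window is discarded by QC).
#' @param session_start session start as a `POSIXct` or a string parseable
#'   as UTC datetime.  All subjects share one local clock.
#' @param clamp two-element numeric, sensor reporting range in mmol/l.
#' @param smbg list with elements `per_day` (readings per day),
#'   `times_hour` (nominal clock hours of the readings), `jitter_sd_min`
#'   (SD of the Gaussian timing jitter in minutes) and `cv` (multiplicative
#'   lognormal measurement noise, coefficient of variation).
#' @param seed master seed; per-subject, per-stage streams are derived from
#'   it deterministically.
#' @return an object of class `generator_config`.
#' @seealso [cgm_study_config()], [questionnaire_study_config()]
#' @export
generator_config <- function(groups,
                             interval_min = 5,
                             recording_days = 4.25,
                             session_start = "2023-03-06 12:00:00",
                             clamp = c(1.1, 33.3),
                             smbg = list(per_day = 4,
                                         times_hour = c(7.5, 12, 17.5, 21.5),
                                         jitter_sd_min = 30,
                                         cv = 0.05),
                             seed = 42L) {
  cfg <- structure(
    list(groups = groups,
         interval_min = interval_min,
         recording_days = recording_days,
         session_start = as_utc(session_start),
         clamp = clamp,
         smbg = smbg,
         seed = as.integer(seed)),
    class = "generator_config")
  validate_config(cfg)
  cfg
}

#' Define one C-peptide group for the generator
#'
#' @param label group label (e.g. `"low"`, `"high"`).
#' @param n number of subjects.
#' @param cpeptide_range two-element numeric, pmol/l; subjects' random
#'   C-peptide values are drawn uniformly from it.  Must sit entirely on
#'   one side of the 200 pmol/l severe-insulin-deficiency threshold.
#' @param trace list of background-trace parameters: `baseline_mean`
#'   (group mean glucose, mmol/l), `between_subject_sd` (SD of per-subject
#'   baseline means, mmol/l), `circadian_amp` (mmol/l) and
#'   `acrophase_hour` (clock hour of the circadian peak),
#'   `ou_theta_per_hr` (OU mean-reversion rate, 1/h), `ou_sd` (stationary
#'   SD of the OU component, mmol/l), `floor` (counter-regulatory floor
#'   applied to the background process, mmol/l).
#' @param excursions list of excursion-process parameters:
#'   `rate_per_week`, `dur_mean_min`, `dur_cv`, `dur_range` (truncation
#'   bounds, minutes), `p_deep` (probability an excursion's nadir is drawn
#'   from the deep range), `deep_nadir` / `shallow_nadir` (uniform ranges,
#'   mmol/l), `p_night_deep` (probability a deep excursion is confined to
#'   the 00:00-08:00 night window), `ramp_min` (half-cosine onset/offset
#'   ramp length, minutes).
#' @param covariates list of covariate distributions used by
#'   [generate_subjects()]: `age_mean`, `age_sd`, `hba1c_mean`, `hba1c_sd`
#'   (mmol/mol), `p_male`, `p_prandial`, `dose_mean`, `dose_sd` (U/kg/day),
#'   `diabetes_type`.
#' @param questionnaire list: `q5_mean` / `q6_mean` (true monthly rates of
#'   symptomatic / asymptomatic hypoglycaemia), `q3_mean` / `q4_mean`
#'   (yearly rates of assistance-requiring and unconsciousness/seizure
#'   episodes), `item_p` (per-item probability of a reduced-awareness
#'   answer, length 1 or 7).
#' @return a list of class `group_config`.
#' @export
group_config <- function(label, n, cpeptide_range,
                         trace, excursions,
                         covariates = NULL, questionnaire = NULL) {
  structure(list(label = label, n = as.integer(n),
                 cpeptide_range = cpeptide_range,
                 trace = trace, excursions = excursions,
                 covariates = covariates, questionnaire = questionnaire),
            class = "group_config")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC")
  if (is.na(out)) stop("config error: unparseable session_start: ", x)
  out
}

#' Validate a generator configuration
#'
#' Checks the structural invariants (non-negative rates, SDs, amplitudes
#' and durations; sampling interval dividing 60; at least one recording
#' day; positive nadir support) and stops with a descriptive error on the
#' first violation.
#'
#' @param cfg a `generator_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config error: ", ..., call. = FALSE)
  if (!length(cfg$groups)) fail("no groups defined")
  if (!is.numeric(cfg$interval_min) || cfg$interval_min <= 0 ||
      60 %% cfg$interval_min != 0)
    fail("interval_min must be a positive divisor of 60")
  if (cfg$recording_days < 1) fail("recording_days must be >= 1")
  if (length(cfg$clamp) != 2 || cfg$clamp[1] <= 0 || diff(cfg$clamp) <= 0)
    fail("clamp must be an increasing positive pair")
  if (cfg$smbg$per_day < 0) fail("smbg per_day must be >= 0")
  if (cfg$smbg$cv < 0) fail("smbg cv must be >= 0")
  for (g in cfg$groups) {
    lbl <- g$label
    tr <- g$trace
    for (nm in c("between_subject_sd", "circadian_amp", "ou_theta_per_hr",
                 "ou_sd"))
      if (tr[[nm]] < 0) fail(lbl, ": trace$", nm, " must be >= 0")
    if (tr$baseline_mean <= 0) fail(lbl, ": baseline_mean must be > 0")
    ex <- g$excursions
    if (ex$rate_per_week < 0) fail(lbl, ": excursion rate must be >= 0")
    if (ex$dur_mean_min < 0 || ex$dur_cv < 0)
      fail(lbl, ": excursion durations must be >= 0")
    if (any(ex$deep_nadir <= 0) || any(ex$shallow_nadir <= 0))
      fail(lbl, ": nadir support must be > 0 mmol/l")
    if (ex$p_deep < 0 || ex$p_deep > 1 ||
        ex$p_night_deep < 0 || ex$p_night_deep > 1)
      fail(lbl, ": excursion probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

# Deterministic per-subject, per-stage stream seed below 2^31.
derive_seed <- function(master, subject_index, stage) {
  as.integer((as.double(master) * 7919 + subject_index * 7907 +
                stage * 104729) %% 2147483629)
}

#' Default configuration of the CGM study cohort
#'
#' Two groups of 17 insulin-treated subjects with type 2 diabetes:
#' severe insulin deficiency (random C-peptide < 200 pmol/l) and
#' preserved secretion (> 600 pmol/l), matched on mean glucose but
#' differing in within-subject variability and in the rate, depth and
#' duration of hypoglycaemic excursions.  The trace-model constants are
#' calibrated (see [calibrate_ou_sd()]) so that the simulated per-subject
#' SD of glucose and the detected episode rates and durations at the
#' 4.0 mmol/l threshold reproduce the study-scale group summaries.
#'
#' @param seed master seed.
#' @return a `generator_config`.
#' @export
cgm_study_config <- function(seed = 42L) {
  low_cov <- list(age_mean = 72.8, age_sd = 9.2, hba1c_mean = 72.0,
                  hba1c_sd = 13.4, p_male = 0.65, p_prandial = 1.00,
                  dose_mean = 0.71, dose_sd = 0.20,
                  diabetes_type = "type2")
  high_cov <- list(age_mean = 71.8, age_sd = 6.8, hba1c_mean = 72.2,
                   hba1c_sd = 12.6, p_male = 0.65, p_prandial = 0.59,
                   dose_mean = 0.52, dose_sd = 0.25,
                   diabetes_type = "type2")
  low <- group_config(
    label = "low", n = 17, cpeptide_range = c(5, 190),
    trace = list(baseline_mean = 10.2, between_subject_sd = 1.5,
                 circadian_amp = 1.2, acrophase_hour = 8,
                 ou_theta_per_hr = 0.5, ou_sd = 4.16, floor = 4.2),
    excursions = list(rate_per_week = 5.5, dur_mean_min = 114.5,
                      dur_cv = 0.5, dur_range = c(25, 420),
                      p_deep = 1.8 / 5.5,
                      deep_nadir = c(1.9, 3.0), shallow_nadir = c(3.05, 3.9),
                      p_night_deep = 0, ramp_min = 20),
    covariates = low_cov,
    questionnaire = list(q5_mean = 3.5, q6_mean = 1.4,
                         q3_mean = 0.5, q4_mean = 0.25, item_p = 0.30))
  high <- group_config(
    label = "high", n = 17, cpeptide_range = c(610, 1600),
    trace = list(baseline_mean = 9.9, between_subject_sd = 1.5,
                 circadian_amp = 1.2, acrophase_hour = 8,
                 ou_theta_per_hr = 0.5, ou_sd = 2.88, floor = 4.2),
    excursions = list(rate_per_week = 2.1, dur_mean_min = 106,
                      dur_cv = 0.5, dur_range = c(25, 420),
                      p_deep = 0.4 / 2.1,
                      deep_nadir = c(1.9, 3.0), shallow_nadir = c(3.05, 3.9),
                      p_night_deep = 1, ramp_min = 20),
    covariates = high_cov,
    questionnaire = list(q5_mean = 1.8, q6_mean = 0.69,
                         q3_mean = 0.4, q4_mean = 0.05, item_p = 0.15))
  generator_config(groups = list(low = low, high = high), seed = seed)
}

#' Default configuration of the questionnaire study cohort
#'
#' 256 insulin-treated subjects with type 2 diabetes split by random
#' C-peptide at 200 pmol/l: 35 below and 221 at or above.  Only the
#' questionnaire response model and covariates matter for this study;
#' the trace model is carried along so the same machinery can simulate
#' CGM for these subjects when asked.
#'
#' @param seed master seed.
#' @return a `generator_config`.
#' @export
questionnaire_study_config <- function(seed = 42L) {
  base <- cgm_study_config(seed = seed)
  low <- base$groups$low
  high <- base$groups$high
  low$n <- 35L
  low$cpeptide_range <- c(5, 190)
  low$covariates <- list(age_mean = 68.2, age_sd = 11.2, hba1c_mean = 71.3,
                         hba1c_sd = 15.8, p_male = 0.60, p_prandial = 0.84,
                         dose_mean = 0.73, dose_sd = 0.42,
                         diabetes_type = "type2")
  high$n <- 221L
  high$cpeptide_range <- c(210, 1600)
  high$covariates <- list(age_mean = 66.0, age_sd = 13.5, hba1c_mean = 66.9,
                          hba1c_sd = 16.5, p_male = 0.63, p_prandial = 0.44,
                          dose_mean = 0.63, dose_sd = 0.48,
                          diabetes_type = "type2")
  generator_config(groups = list(low = low, high = high), seed = base$seed)
}

#' Read / write a flat key-value configuration file
#'
#' The on-disk format is one `key = value` pair per line, keys using `$`
#' to path into the nested configuration (e.g.
#' `groups$low$excursions$rate_per_week = 5.5`).  Values are parsed as
#' numeric vectors where possible (comma separated), otherwise strings.
#' Unknown keys are an error.  Writing serialises only leaves that differ
#' from nothing -- the full configuration is always written.
#'
#' @param path file path.
#' @param base configuration to overlay the file's entries onto
#'   (default [cgm_study_config()]).
#' @return `read_config()`: a validated `generator_config`.
#' @export
read_config <- function(path, base = cgm_study_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- unclass(base)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("config error: malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- strsplit(key, "$", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    parsed <- if (!anyNA(num)) num else val
    cfg <- assign_path(cfg, parts, parsed, key)
  }
  cfg$session_start <- as_utc(cfg$session_start)
  cfg <- structure(cfg, class = "generator_config")
  validate_config(cfg)
  cfg
}

assign_path <- function(x, parts, value, key) {
  if (is.null(x[[parts[1]]]))
    stop("config error: unknown key: ", key)
  if (length(parts) == 1) {
    x[[parts[1]]] <- value
  } else {
    x[[parts[1]]] <- assign_path(x[[parts[1]]], parts[-1], value, key)
  }
  x
}

#' @rdname read_config
#' @param cfg configuration to write.
#' @export
write_config <- function(cfg, path) {
  flat <- character(0)
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = "$") else nm
      if (is.list(v)) {
        walk(v, key)
      } else if (inherits(v, "POSIXct")) {
        flat <<- c(flat, paste0(key, " = ",
                                format(v, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
      } else {
        flat <<- c(flat, paste0(key, " = ", paste(v, collapse = ",")))
      }
    }
  }
  walk(unclass(cfg), "")
  writeLines(flat, path)
  invisible(path)
}
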