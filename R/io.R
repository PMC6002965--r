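TIME_FMT <- "%Y-%m-%dT%H:%M:%SZ"

fmt_time <- function(x) format(x, TIME_FMT, tz = "UTC")

parse_time <- function(x, file) {
  out <- as.POSIXct(x, format = TIME_FMT, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("schema error in ", file, ": unparseable timestamp at row ",
         bad[1], ": '", x[bad[1]], "'")
  out
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", file, ": missing column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

check_numeric <- function(df, cols, file, positive = character(0)) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop("schema error in ", file, ": column '", cl, "' must be numeric")
    if (cl %in% positive && any(v[!is.na(v)] <= 0))
      stop("schema error in ", file, ": column '", cl,
           "' must be > 0 (row ",
           which(!is.na(v) & v <= 0)[1], ")")
  }
  invisible(df)
}

#' Write a cohort to the CSV interchange files
#'
#' Writes `subjects.csv`, `cgm.csv` (`subject_id`, ISO-8601 `timestamp`,
#' `glucose_mmol_l`; missing samples as empty fields), `smbg.csv` and
#' `clarke.csv` into `dir`.  All glucose values are mmol/l; timestamps
#' are UTC.
#'
#' @param cohort a cohort list from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  cgm <- do.call(rbind, lapply(cohort$traces, function(tr)
    data.frame(subject_id = tr$subject_id,
               timestamp = fmt_time(trace_times(tr)),
               glucose_mmol_l = tr$glucose)))
  if (is.null(cgm))
    cgm <- data.frame(subject_id = character(0), timestamp = character(0),
                      glucose_mmol_l = numeric(0))
  utils::write.csv(cgm, file.path(dir, "cgm.csv"), row.names = FALSE)
  smbg <- cohort$smbg
  if (is.null(smbg))
    smbg <- data.frame(subject_id = character(0),
                       time = as.POSIXct(character(0)), glucose = numeric(0))
  utils::write.csv(data.frame(subject_id = smbg$subject_id,
                              timestamp = fmt_time(smbg$time),
                              glucose_mmol_l = smbg$glucose),
                   file.path(dir, "smbg.csv"), row.names = FALSE)
  utils::write.csv(cohort$clarke, file.path(dir, "clarke.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read CGM traces from `cgm.csv`
#'
#' Validates the schema (`subject_id`, `timestamp`, `glucose_mmol_l`),
#' checks each subject's grid is uniform, and rebuilds `glucose_trace`
#' objects (gaps may be encoded either as empty glucose fields or as
#' absent rows; absent rows are refilled as explicit `NA`s).
#'
#' @param path path to `cgm.csv`.
#' @return named list of `glucose_trace` objects.
#' @export
read_cgm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "timestamp", "glucose_mmol_l"), path)
  check_numeric(df, "glucose_mmol_l", path, positive = "glucose_mmol_l")
  df$time <- parse_time(df$timestamp, path)
  out <- list()
  for (sid in unique(df$subject_id)) {
    d <- df[df$subject_id == sid, ]
    d <- d[order(d$time), ]
    gaps <- as.numeric(diff(d$time), units = "mins")
    dt <- min(gaps)
    if (any(gaps %% dt != 0))
      stop("schema error in ", path, ": subject ", sid,
           " is not on a uniform ", dt, "-min grid")
    n <- as.numeric(difftime(d$time[nrow(d)], d$time[1], units = "mins")) /
      dt + 1
    g <- rep(NA_real_, n)
    g[round(as.numeric(difftime(d$time, d$time[1], units = "mins")) / dt) + 1] <-
      d$glucose_mmol_l
    out[[sid]] <- glucose_trace(sid, d$time[1], dt, g)
  }
  out
}

#' Read SMBG readings from `smbg.csv`
#' @param path path to `smbg.csv`.
#' @return data frame with `subject_id`, `time`, `glucose`.
#' @export
read_smbg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "timestamp", "glucose_mmol_l"), path)
  check_numeric(df, "glucose_mmol_l", path, positive = "glucose_mmol_l")
  data.frame(subject_id = df$subject_id,
             time = parse_time(df$timestamp, path),
             glucose = df$glucose_mmol_l)
}

#' Read the subject metadata table from `subjects.csv`
#' @param path path to `subjects.csv`.
#' @return data frame in the [generate_subjects()] layout.
#' @export
read_subjects_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "group", "cpeptide_pmol_l"), path)
  check_numeric(df, "cpeptide_pmol_l", path)
  if (any(df$cpeptide_pmol_l < 0))
    stop("schema error in ", path, ": C-peptide must be >= 0")
  df
}

#' Read Clarke questionnaire responses from `clarke.csv`
#'
#' Validates that the seven items are binary and the frequency
#' categories belong to the documented vocabulary.
#'
#' @param path path to `clarke.csv`.
#' @return data frame in the [generate_questionnaire()] layout.
#' @export
read_clarke_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", paste0("item", 1:7),
                      "q3_count", "q4_count", "q5_category", "q6_category"),
                path)
  for (i in 1:7) {
    v <- df[[paste0("item", i)]]
    if (!all(v %in% c(0, 1)))
      stop("schema error in ", path, ": item", i, " must be 0/1 (row ",
           which(!(v %in% c(0, 1)))[1], ")")
  }
  recode_frequency(df$q5_category)  # validates the vocabulary
  recode_frequency(df$q6_category)
  df
}
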