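#' Draw the subject metadata table for a configured cohort
#'
#' C-peptide is uniform on each group's configured range; age, HbA1c and
#' insulin dose are Gaussian with the configured group moments (truncated
#' to plausible positive supports); sex and prandial/mixed-insulin use
#' are Bernoulli.
#'
#' @param cfg a `generator_config`.
#' @return data frame, one row per subject: `subject_id`, `group`,
#'   `cpeptide_pmol_l`, `age_years`, `sex`, `hba1c_mmol_mol`,
#'   `prandial_insulin`, `insulin_dose_u_kg`, `diabetes_type`.
#' @export
generate_subjects <- function(cfg) {
  validate_config(cfg)
  rows <- list()
  idx <- 0L
  for (grp in cfg$groups) {
    cov <- grp$covariates
    if (is.null(cov))
      cov <- list(age_mean = 70, age_sd = 10, hba1c_mean = 70, hba1c_sd = 14,
                  p_male = 0.6, p_prandial = 0.7, dose_mean = 0.6,
                  dose_sd = 0.25, diabetes_type = "type2")
    for (i in seq_len(grp$n)) {
      idx <- idx + 1L
      set.seed(derive_seed(cfg$seed, idx, 1))
      rows[[idx]] <- data.frame(
        subject_id = sprintf("S%03d", idx),
        group = grp$label,
        cpeptide_pmol_l = stats::runif(1, grp$cpeptide_range[1],
                                       grp$cpeptide_range[2]),
        age_years = max(35, stats::rnorm(1, cov$age_mean, cov$age_sd)),
        sex = if (stats::runif(1) < cov$p_male) "M" else "F",
        hba1c_mmol_mol = max(40, stats::rnorm(1, cov$hba1c_mean, cov$hba1c_sd)),
        prandial_insulin = stats::runif(1) < cov$p_prandial,
        insulin_dose_u_kg = max(0.1, stats::rnorm(1, cov$dose_mean,
                                                  cov$dose_sd)),
        diabetes_type = cov$diabetes_type)
    }
  }
  out <- do.call(rbind, rows)
  check_cpeptide_groups(out)
  out
}

# group labels must be consistent with the 200 / 600 pmol/l thresholds
check_cpeptide_groups <- function(subjects) {
  low_bad <- subjects$group == "low" & subjects$cpeptide_pmol_l >= 200
  high_bad <- subjects$group == "high" & subjects$cpeptide_pmol_l < 200
  if (any(low_bad | high_bad))
    stop("config error: C-peptide values inconsistent with group thresholds")
  invisible(subjects)
}

#' The Clarke frequency-category vocabulary
#'
#' Canonical labels, in increasing frequency order, of the questionnaire's
#' question 5 / question 6 monthly-frequency categories.
#' @return character vector of length 6.
#' @export
clarke_categories <- function() {
  c("none", "1-3 per month", "1 per week", "2-3 per week",
    "4-5 per week", "almost daily")
}

#' Simulate one subject's Clarke questionnaire response
#'
#' True monthly counts of symptomatic (Q5) and asymptomatic (Q6)
#' hypoglycaemia are Poisson with the group means; each count is mapped
#' to the frequency category whose recoded monthly value (see
#' [recode_frequency()]) is nearest, ties resolved to the lower
#' category.  The seven binary awareness items are independent Bernoulli
#' draws with the configured per-item probabilities; Q3 (assistance
#' required) and Q4 (unconsciousness/seizure) are Poisson yearly counts.
#'
#' @param subject a row of the subject table.
#' @param cfg a `generator_config`.
#' @param seed integer stream seed.
#' @return one-row data frame: `subject_id`, `item1`..`item7`,
#'   `q3_count`, `q4_count`, `q5_category`, `q6_category`.
#' @export
generate_questionnaire <- function(subject, cfg, seed) {
  grp <- cfg$groups[[as.character(subject$group)]]
  if (is.null(grp) || is.null(grp$questionnaire))
    stop("config error: no questionnaire parameters for group '",
         subject$group, "'")
  q <- grp$questionnaire
  set.seed(as.integer(seed))
  p <- rep_len(q$item_p, 7)
  items <- stats::rbinom(7, 1, p)
  k5 <- stats::rpois(1, q$q5_mean)
  k6 <- stats::rpois(1, q$q6_mean)
  k3 <- stats::rpois(1, q$q3_mean)
  k4 <- stats::rpois(1, q$q4_mean)
  out <- data.frame(subject_id = subject$subject_id)
  for (i in 1:7) out[[paste0("item", i)]] <- items[i]
  out$q3_count <- k3
  out$q4_count <- k4
  out$q5_category <- count_to_category(k5)
  out$q6_category <- count_to_category(k6)
  out
}

#' Map a monthly episode count to the nearest Clarke frequency category
#'
#' Chooses the category whose recoded monthly value is closest to the
#' count; ties go to the lower category.
#'
#' @param count non-negative monthly episode count.
#' @return a category label from [clarke_categories()].
#' @export
count_to_category <- function(count) {
  cats <- clarke_categories()
  vals <- vapply(cats, recode_frequency, numeric(1))
  cats[which.min(abs(vals - count))]   # which.min takes the first (lower) tie
}

#' Generate a complete synthetic cohort
#'
#' Draws the subject table, per-subject CGM traces (with ground-truth
#' excursion logs), SMBG calibration readings and Clarke questionnaire
#' responses.  Per-subject random streams are derived deterministically
#' from the master seed, so the whole cohort is a pure function of the
#' configuration.
#'
#' @param cfg a `generator_config`.
#' @param out_dir if non-`NULL`, the interchange CSV files
#'   (`subjects.csv`, `cgm.csv`, `smbg.csv`, `clarke.csv`) are written
#'   there.
#' @param traces set `FALSE` to skip CGM/SMBG simulation (questionnaire
#'   study at large n).
#' @return list with elements `subjects` (data frame), `traces` (named
#'   list of `glucose_trace`), `events` (ground-truth excursion log),
#'   `smbg` (data frame), `clarke` (data frame), `config`.
#' @export
generate_cohort <- function(cfg, out_dir = NULL, traces = TRUE) {
  subjects <- generate_subjects(cfg)
  n <- nrow(subjects)
  trace_list <- list()
  smbg_list <- list()
  clarke_list <- list()
  event_list <- list()
  for (i in seq_len(n)) {
    subj <- subjects[i, ]
    if (traces) {
      tr <- generate_trace(subj, cfg, derive_seed(cfg$seed, i, 2))
      trace_list[[subj$subject_id]] <- tr
      ev <- attr(tr, "events")
      if (nrow(ev)) {
        ev$subject_id <- subj$subject_id
        event_list[[subj$subject_id]] <- ev
      }
      smbg_list[[i]] <- generate_smbg(tr, cfg, derive_seed(cfg$seed, i, 3))
    }
    clarke_list[[i]] <- generate_questionnaire(subj, cfg,
                                               derive_seed(cfg$seed, i, 4))
  }
  cohort <- list(subjects = subjects,
                 traces = trace_list,
                 events = if (length(event_list))
                   do.call(rbind, unname(event_list)) else NULL,
                 smbg = if (length(smbg_list))
                   do.call(rbind, smbg_list) else NULL,
                 clarke = do.call(rbind, clarke_list),
                 config = cfg)
  if (!is.null(out_dir)) write_cohort_csv(cohort, out_dir)
  cohort
}
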