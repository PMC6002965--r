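#' Run the CGM arm: QC, metrics and episode detection per subject
#'
#' @param traces named list of `glucose_trace` objects.
#' @param smbg SMBG data frame covering all subjects.
#' @param thresholds episode thresholds in mmol/l.
#' @return list with `qc` (per-subject retained time and exclusion flag),
#'   `qc_windows` (all window rows), `metrics` (one row per retained
#'   subject), `episodes`, `hypo` (per subject x threshold summary).
#' @export
analyze_cgm <- function(traces, smbg, thresholds = c(4, 3, 2.2)) {
  qc_rows <- list()
  win_rows <- list()
  metric_rows <- list()
  episode_rows <- list()
  hypo_rows <- list()
  for (tr in traces) {
    sid <- tr$subject_id
    rd <- smbg[smbg$subject_id == sid, , drop = FALSE]
    qc <- apply_qc(tr, rd)
    qc_rows[[sid]] <- data.frame(subject_id = sid,
                                 retained_hours = qc$retained_hours,
                                 retained_days = qc$retained_days,
                                 excluded = qc$excluded)
    win_rows[[sid]] <- qc$report
    if (qc$excluded) next
    metric_rows[[sid]] <- compute_metrics(qc$segments, sid)
    eps <- do.call(rbind, lapply(thresholds, function(th)
      detect_episodes(qc$segments, th)))
    episode_rows[[sid]] <- eps
    hypo_rows[[sid]] <- summarize_hypo(eps, qc$retained_hours, sid,
                                       thresholds = thresholds)
  }
  list(qc = do.call(rbind, unname(qc_rows)),
       qc_windows = do.call(rbind, unname(win_rows)),
       metrics = do.call(rbind, unname(metric_rows)),
       episodes = do.call(rbind, unname(episode_rows)),
       hypo = do.call(rbind, unname(hypo_rows)))
}

group_mean_ci <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n) else NA
  c(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Group-level CGM summaries and low-vs-high contrasts
#'
#' Produces the per-group means (mean glucose, SD, MAGE, LBGI, episode
#' rates and durations at each threshold, with day/night split) and the
#' study contrasts: paired t tests on the variability metrics (subjects
#' are matched by position within group), a chi-square test on the
#' proportion experiencing at least one episode, and rate-ratio z tests
#' on pooled episode counts with exact Poisson CIs per group.
#'
#' @param analysis result of [analyze_cgm()].
#' @param subjects subject metadata table.
#' @param thresholds thresholds to contrast.
#' @return list with `group_summary` (data frame) and `comparisons`
#'   (stacked `group_comparison` rows).
#' @export
compare_cgm_groups <- function(analysis, subjects,
                               thresholds = c(4, 3, 2.2)) {
  met <- merge(analysis$metrics, subjects[, c("subject_id", "group")],
               by = "subject_id")
  hyp <- merge(analysis$hypo, subjects[, c("subject_id", "group")],
               by = "subject_id")
  groups <- unique(subjects$group)

  sum_rows <- list()
  for (g in groups) {
    mg <- met[met$group == g, ]
    for (v in c("mean_glucose", "sd_glucose", "mage", "lbgi")) {
      ci <- group_mean_ci(mg[[v]])
      sum_rows[[length(sum_rows) + 1]] <-
        data.frame(group = g, quantity = v, threshold = NA_real_,
                   mean = ci["mean"], ci_lower = ci["lower"],
                   ci_upper = ci["upper"], n = ci["n"])
    }
    for (th in thresholds) {
      hg <- hyp[hyp$group == g & hyp$threshold == th, ]
      for (v in c("rate_per_week", "duration_min_per_week",
                  "day_rate", "night_rate")) {
        ci <- group_mean_ci(hg[[v]])
        sum_rows[[length(sum_rows) + 1]] <-
          data.frame(group = g, quantity = v, threshold = th,
                     mean = ci["mean"], ci_lower = ci["lower"],
                     ci_upper = ci["upper"], n = ci["n"])
      }
      sum_rows[[length(sum_rows) + 1]] <-
        data.frame(group = g, quantity = "prop_any_episode", threshold = th,
                   mean = mean(hg$count >= 1), ci_lower = NA, ci_upper = NA,
                   n = nrow(hg))
    }
  }
  group_summary <- do.call(rbind, sum_rows)
  rownames(group_summary) <- NULL

  cmps <- list()
  if (length(groups) == 2) {
    g1 <- groups[1]
    g2 <- groups[2]
    m1 <- met[met$group == g1, ]
    m2 <- met[met$group == g2, ]
    n_pair <- min(nrow(m1), nrow(m2))
    for (v in c("mean_glucose", "sd_glucose", "mage", "lbgi")) {
      d <- m1[[v]][seq_len(n_pair)] - m2[[v]][seq_len(n_pair)]
      d <- d[!is.na(d)]
      if (length(d) >= 2 && stats::sd(d) > 0)
        cmps[[length(cmps) + 1]] <- paired_t(d, outcome = v)
    }
    for (th in thresholds) {
      h1 <- hyp[hyp$group == g1 & hyp$threshold == th, ]
      h2 <- hyp[hyp$group == g2 & hyp$threshold == th, ]
      a <- sum(h1$count >= 1)
      b <- nrow(h1) - a
      cc <- sum(h2$count >= 1)
      dd <- nrow(h2) - cc
      if ((a + b) > 0 && (cc + dd) > 0 && (a + cc) > 0 && (b + dd) > 0)
        cmps[[length(cmps) + 1]] <-
          chi_square_2x2(a, b, cc, dd,
                         outcome = sprintf("any episode <= %.1f mmol/l", th))
      cmps[[length(cmps) + 1]] <-
        rate_compare(sum(h1$count), sum(h1$exposure_weeks),
                     sum(h2$count), sum(h2$exposure_weeks),
                     outcome = sprintf("episode rate <= %.1f mmol/l", th))
    }
  }
  comparisons <- do.call(rbind, cmps)
  list(group_summary = group_summary, comparisons = comparisons)
}

#' Questionnaire-arm analysis: scoring, rates and contrasts
#'
#' Scores every response, recodes the question 5 / question 6 monthly
#' rates, and contrasts C-peptide groups: rate-ratio z tests on total
#' reported episodes per person-month (with exact Poisson CIs per
#' group), chi-square tests on reduced awareness and on any question 3 /
#' question 4 episode, and (optionally) covariate-adjusted logistic and
#' Poisson regressions.
#'
#' @param clarke questionnaire response table.
#' @param subjects subject metadata table.
#' @param adjust covariate names for the adjusted models; `NULL` skips
#'   them.
#' @return list with `scored`, `group_summary`, `comparisons`.
#' @export
analyze_questionnaire <- function(clarke, subjects,
                                  adjust = c("age_years", "sex",
                                             "hba1c_mmol_mol",
                                             "prandial_insulin")) {
  scored <- score_clarke_table(clarke)
  dat <- merge(scored, subjects, by = "subject_id")
  dat$low_cpeptide <- factor(dat$group == "low", levels = c(FALSE, TRUE),
                             labels = c("high", "low"))
  groups <- c("low", "high")
  sum_rows <- list()
  for (g in groups) {
    dg <- dat[dat$group == g, ]
    if (!nrow(dg)) next
    for (v in c("q5_rate_month", "q6_rate_month")) {
      ci <- poisson_rate_ci(sum(dg[[v]]), nrow(dg))
      sum_rows[[length(sum_rows) + 1]] <-
        data.frame(group = g, quantity = v, mean = ci$rate,
                   ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
                   n = nrow(dg))
    }
    for (v in c("reduced_awareness", "q3_any", "q4_any"))
      sum_rows[[length(sum_rows) + 1]] <-
        data.frame(group = g, quantity = v, mean = mean(dg[[v]]),
                   ci_lower = NA, ci_upper = NA, n = nrow(dg))
  }
  cmps <- list()
  d_lo <- dat[dat$group == "low", ]
  d_hi <- dat[dat$group == "high", ]
  if (nrow(d_lo) && nrow(d_hi)) {
    for (v in c("q5_rate_month", "q6_rate_month"))
      cmps[[length(cmps) + 1]] <-
        rate_compare(sum(d_lo[[v]]), nrow(d_lo),
                     sum(d_hi[[v]]), nrow(d_hi), outcome = v)
    for (v in c("reduced_awareness", "q3_any", "q4_any")) {
      a <- sum(d_lo[[v]])
      b <- nrow(d_lo) - a
      cc <- sum(d_hi[[v]])
      dd <- nrow(d_hi) - cc
      if ((a + cc) > 0 && (b + dd) > 0)
        cmps[[length(cmps) + 1]] <- chi_square_2x2(a, b, cc, dd, outcome = v)
    }
    if (!is.null(adjust)) {
      dat$q5q6_total <- dat$q5_rate_month + dat$q6_rate_month
      dat$person_months <- 1
      cmps[[length(cmps) + 1]] <-
        adjusted_models(dat, "q5q6_total", "low_cpeptide", adjust,
                        family = "poisson", offset = "person_months")
      for (v in c("reduced_awareness", "q4_any"))
        if (sum(dat[[v]]) > 0 && sum(!dat[[v]]) > 0)
          cmps[[length(cmps) + 1]] <-
            adjusted_models(dat, v, "low_cpeptide", adjust,
                            family = "binomial")
    }
  }
  list(scored = scored,
       group_summary = do.call(rbind, sum_rows),
       comparisons = do.call(rbind, cmps))
}

#' Run the full pipeline on simulated or user-supplied data
#'
#' Orchestrates simulate -> QC -> metrics -> episodes -> questionnaire
#' scoring -> group contrasts and assembles a machine-readable report.
#' With `inputs = NULL` a cohort is simulated from `config`; otherwise
#' `inputs` must name the interchange CSV files to analyse
#' (`subjects`, `cgm`, `smbg`, `clarke` as needed by `mode`).
#'
#' @param config a `generator_config` (or path to a flat key-value
#'   config file).
#' @param mode `"cgm-study"`, `"questionnaire-study"` or `"both"`.
#' @param inputs optional named list of CSV paths to analyse instead of
#'   simulating.
#' @param out_dir if non-`NULL`, result tables (`metrics.csv`,
#'   `episodes.csv`, `hypo_summary.csv`, `qc_report.csv`,
#'   `clarke_scored.csv`, `comparisons.csv`) and `report.json` /
#'   `report.txt` are written there.
#' @param seed overrides the config's master seed.
#' @return a list of class `pipeline_run` with the stage outputs, the
#'   config snapshot and the rendered report lines.
#' @export
run_pipeline <- function(config = cgm_study_config(),
                         mode = c("cgm-study", "questionnaire-study", "both"),
                         inputs = NULL, out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  run <- list(config = config, mode = mode, seed = config$seed)

  want_cgm <- mode %in% c("cgm-study", "both")
  if (is.null(inputs)) {
    cohort <- generate_cohort(config, traces = want_cgm)
    subjects <- cohort$subjects
  } else {
    subjects <- read_subjects_csv(inputs$subjects)
    cohort <- list(
      subjects = subjects,
      traces = if (want_cgm) read_cgm_csv(inputs$cgm) else list(),
      smbg = if (want_cgm) read_smbg_csv(inputs$smbg) else NULL,
      clarke = if (!is.null(inputs$clarke)) read_clarke_csv(inputs$clarke)
      else NULL)
  }
  run$subjects <- subjects

  if (want_cgm) {
    ana <- analyze_cgm(cohort$traces, cohort$smbg)
    cmp <- compare_cgm_groups(ana, subjects)
    run$cgm <- c(ana, cmp)
  }
  if (mode %in% c("questionnaire-study", "both") && !is.null(cohort$clarke))
    run$questionnaire <- analyze_questionnaire(cohort$clarke, subjects)

  run$report <- render_report(run)
  class(run) <- "pipeline_run"
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(run$cgm)) {
    wr(run$cgm$metrics, "metrics.csv")
    wr(run$cgm$episodes, "episodes.csv")
    wr(run$cgm$hypo, "hypo_summary.csv")
    wr(as.data.frame(run$cgm$qc_windows), "qc_report.csv")
    wr(run$cgm$comparisons, "comparisons.csv")
    wr(run$cgm$group_summary, "group_summary.csv")
  }
  if (!is.null(run$questionnaire)) {
    wr(run$questionnaire$scored, "clarke_scored.csv")
    wr(run$questionnaire$comparisons, "clarke_comparisons.csv")
  }
  json <- list(mode = run$mode, seed = run$seed)
  if (!is.null(run$cgm)) json$cgm_summary <- run$cgm$group_summary
  if (!is.null(run$questionnaire))
    json$questionnaire_summary <- run$questionnaire$group_summary
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(run$report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a plain-text summary report
#'
#' Three panels per threshold for the CGM arm (proportion with one or
#' more episodes, episode rate, duration) plus the variability metrics,
#' and the questionnaire-arm rates when present.
#'
#' @param run a `pipeline_run` (or the partial list built inside
#'   [run_pipeline()]).
#' @return character vector of report lines.
#' @export
render_report <- function(run) {
  ln <- c(sprintf("== cgmhypo report (mode %s, seed %d) ==",
                  run$mode, run$seed))
  fmt <- function(m, lo, hi)
    if (is.na(lo)) sprintf("%.2f", m) else
      sprintf("%.2f (%.2f, %.2f)", m, lo, hi)
  if (!is.null(run$cgm)) {
    gs <- run$cgm$group_summary
    ln <- c(ln, "", "-- CGM arm --",
            sprintf("subjects analysed: %s",
                    paste(sprintf("%s n=%d", unique(gs$group),
                                  tapply(gs$n, gs$group, max)[unique(gs$group)]),
                          collapse = ", ")))
    for (q in c("mean_glucose", "sd_glucose", "mage", "lbgi")) {
      rows <- gs[gs$quantity == q, ]
      ln <- c(ln, sprintf("%-22s %s", q,
                          paste(sprintf("%s %s", rows$group,
                                        mapply(fmt, rows$mean, rows$ci_lower,
                                               rows$ci_upper)),
                                collapse = " | ")))
    }
    for (q in c("prop_any_episode", "rate_per_week",
                "duration_min_per_week")) {
      rows <- gs[gs$quantity == q, ]
      for (th in unique(rows$threshold)) {
        rt <- rows[rows$threshold == th, ]
        ln <- c(ln, sprintf("%-22s %s",
                            sprintf("%s @%.1f", q, th),
                            paste(sprintf("%s %s", rt$group,
                                          mapply(fmt, rt$mean, rt$ci_lower,
                                                 rt$ci_upper)),
                                  collapse = " | ")))
      }
    }
  }
  if (!is.null(run$questionnaire)) {
    gs <- run$questionnaire$group_summary
    ln <- c(ln, "", "-- questionnaire arm --")
    for (q in unique(gs$quantity)) {
      rows <- gs[gs$quantity == q, ]
      ln <- c(ln, sprintf("%-22s %s", q,
                          paste(sprintf("%s %s", rows$group,
                                        mapply(fmt, rows$mean, rows$ci_lower,
                                               rows$ci_upper)),
                                collapse = " | ")))
    }
    cmp <- run$questionnaire$comparisons
    und <- !is.null(cmp) && any(!is.na(cmp$note) &
                                  startsWith(cmp$note, "unbounded"))
    if (und) ln <- c(ln, "note: a rate ratio is undefined (zero events)")
  }
  ln
}

#' @export
print.pipeline_run <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
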