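#' Replicate the CGM study and aggregate group-level outcomes
#'
#' Simulates the two-group CGM study repeatedly under the packaged
#' default configuration (17 + 17 subjects, ~4 days of 5-min CGM),
#' runs QC, the variability metrics and episode detection on each
#' replicate, and aggregates the per-subject results across subjects and
#' replicates: mean per-subject SD of glucose, and mean episode rate and
#' below-threshold duration per person per week at the 4.0 mmol/l
#' threshold.
#'
#' @param n_reps number of replicate cohorts.
#' @param seed base seed; each replicate uses a seed derived from it.
#' @param config_fn function of one argument (`seed`) returning the
#'   cohort configuration (default [cgm_study_config()]).
#' @return list with `per_rep` (one row per replicate x group) and
#'   `aggregate` (one row per group with `sd_glucose`, `rate_4`,
#'   `duration_4`, `n_subject_reps`).
#' @export
replicate_cgm_study <- function(n_reps = 20, seed = 42L,
                                config_fn = cgm_study_config) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config_fn(seed = derive_seed(seed, r, 30))
    co <- generate_cohort(cfg)
    ana <- suppressWarnings(analyze_cgm(co$traces, co$smbg,
                                        thresholds = 4))
    met <- merge(ana$metrics, co$subjects[, c("subject_id", "group")],
                 by = "subject_id")
    hyp <- merge(ana$hypo, co$subjects[, c("subject_id", "group")],
                 by = "subject_id")
    rows[[r]] <- do.call(rbind, lapply(unique(met$group), function(g) {
      m <- met[met$group == g, ]
      h <- hyp[hyp$group == g & hyp$threshold == 4, ]
      data.frame(rep = r, group = g, n = nrow(m),
                 sd_glucose = mean(m$sd_glucose),
                 mean_glucose = mean(m$mean_glucose),
                 lbgi = mean(m$lbgi),
                 rate_4 = mean(h$rate_per_week),
                 duration_4 = mean(h$duration_min_per_week))
    }))
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$group), function(d)
    data.frame(group = d$group[1],
               sd_glucose = mean(d$sd_glucose),
               mean_glucose = mean(d$mean_glucose),
               lbgi = mean(d$lbgi),
               rate_4 = mean(d$rate_4),
               duration_4 = mean(d$duration_4),
               n_subject_reps = sum(d$n))))
  rownames(agg) <- NULL
  list(per_rep = per_rep, aggregate = agg)
}
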