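test_that("noise-free degenerate config yields a constant trace at the baseline", {
  cfg <- noise_free_config(baseline = 10, rate_per_week = 0)
  subj <- list(subject_id = "S1", group = "low")
  tr <- generate_trace(subj, cfg, 3)
  expect_equal(length(tr$glucose), 4 * 24 * 12)
  expect_true(all(tr$glucose == 10))
  expect_equal(nrow(attr(tr, "events")), 0)
})

test_that("circadian-only trace has SD A/sqrt(2), matching a brute-force period scan", {
  cfg <- noise_free_config(rate_per_week = 0)
  cfg$groups$low$trace$circadian_amp <- 2
  subj <- list(subject_id = "S1", group = "low")
  tr <- generate_trace(subj, cfg, 3)
  # brute-force: population SD over exactly one 24-h period of samples
  one_period <- tr$glucose[1:288]
  brute <- sqrt(mean((one_period - mean(one_period))^2))
  expect_equal(brute, 2 / sqrt(2), tolerance = 1e-6)
  expect_equal(sd(tr$glucose), 2 / sqrt(2), tolerance = 5e-3)
})

test_that("traces are a pure function of (subject, config, seed)", {
  cfg <- cgm_study_config(seed = 5)
  subj <- list(subject_id = "S1", group = "low")
  t1 <- generate_trace(subj, cfg, 17)
  t2 <- generate_trace(subj, cfg, 17)
  t3 <- generate_trace(subj, cfg, 18)
  expect_identical(t1$glucose, t2$glucose)
  expect_identical(attr(t1, "events"), attr(t2, "events"))
  expect_gt(sum(t1$glucose != t3$glucose), 0)
  expect_error(generate_trace(subj, cfg, -1), "seed")
  expect_error(generate_trace(list(subject_id = "S1", group = "nope"), cfg, 1),
               "config error")
})

test_that("with excursions disabled the per-subject SD matches the closed form", {
  cfg <- noise_free_config(rate_per_week = 0, days = 14)
  cfg$groups$low$trace$ou_sd <- 1.4
  cfg$groups$low$trace$circadian_amp <- 1.0
  cfg$groups$low$trace$floor <- 0.1   # keep the floor out of play
  sds <- vapply(1:12, function(i)
    sd(generate_trace(list(subject_id = "S", group = "low"), cfg, i)$glucose),
    numeric(1))
  expect_equal(mean(sds), sqrt(1.4^2 + 1.0^2 / 2), tolerance = 0.05)
})

test_that("zero-rate excursion process leaves the trace unchanged", {
  tr <- make_trace(rep(9, 288))
  params <- noise_free_config()$groups$low$excursions
  params$rate_per_week <- 0
  out <- inject_excursions(tr, params, 4)
  expect_identical(out$glucose, tr$glucose)
  expect_equal(nrow(attr(out, "events")), 0)
})

test_that("injected event counts follow the configured Poisson rate", {
  params <- noise_free_config()$groups$low$excursions  # 5.5 / week
  n_sub <- 400
  weeks <- 4
  counts <- vapply(seq_len(n_sub), function(i) {
    tr <- make_trace(rep(10, weeks * 7 * 288), subject_id = paste0("P", i))
    ev <- attr(inject_excursions(tr, params, 9000 + i), "events")
    nrow(ev)
  }, numeric(1))
  rate_hat <- mean(counts) / weeks
  mc_se <- sqrt(5.5 / (weeks * n_sub))
  expect_lt(abs(rate_hat - 5.5), 2 * mc_se)
})

test_that("night-restricted deep events start and end inside 00:00-08:00", {
  params <- noise_free_config()$groups$low$excursions
  params$p_deep <- 1
  params$p_night_deep <- 1
  # trace starting at midnight so offsets map directly to clock time
  tr <- make_trace(rep(10, 4 * 7 * 288), start = "2023-03-06 00:00:00")
  ev <- attr(inject_excursions(tr, params, 77), "events")
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$nadir <= 3.0))
  start_clock <- ev$start_offset_min %% 1440
  end_clock <- start_clock + ev$span_min
  expect_true(all(start_clock >= 0 & end_clock <= 480))
})

test_that("saturating excursion requests are a configuration error", {
  params <- noise_free_config()$groups$low$excursions
  params$rate_per_week <- 400
  tr <- make_trace(rep(10, 288))
  expect_error(inject_excursions(tr, params, 1), "saturate")
})

test_that("events are pairwise disjoint with > 20 min separation", {
  params <- noise_free_config()$groups$low$excursions
  for (seed in 1:8) {
    tr <- make_trace(rep(10, 4 * 7 * 288))
    ev <- attr(inject_excursions(tr, params, seed), "events")
    if (nrow(ev) < 2) next
    ev <- ev[order(ev$start_offset_min), ]
    gaps <- ev$start_offset_min[-1] -
      (ev$start_offset_min + ev$span_min)[-nrow(ev)]
    expect_true(all(gaps > 20))
  }
})

test_that("noise-free SMBG equals the co-timed sensor values", {
  cfg <- noise_free_config(rate_per_week = 0)
  cfg$smbg$cv <- 0
  tr <- generate_trace(list(subject_id = "S1", group = "low"), cfg, 2)
  sm <- generate_smbg(tr, cfg, 3)
  idx <- round(as.numeric(difftime(sm$time, tr$start, units = "mins")) / 5) + 1
  expect_identical(sm$glucose, tr$glucose[idx])
})

test_that("SMBG scheduling honours readings/day and degenerate inputs", {
  cfg <- noise_free_config(rate_per_week = 0)
  cfg$smbg$jitter_sd_min <- 0
  cfg$smbg$cv <- 0
  tr <- generate_trace(list(subject_id = "S1", group = "low"), cfg, 2)
  expect_equal(nrow(generate_smbg(tr, cfg, 3)), 16)  # 4/day over 4 days
  cfg$smbg$per_day <- 0
  expect_equal(nrow(generate_smbg(tr, cfg, 3)), 0)
})

test_that("questionnaire generation maps drawn counts to consistent categories", {
  cfg <- cgm_study_config()
  cfg$groups$low$questionnaire$q5_mean <- 0
  cfg$groups$low$questionnaire$q6_mean <- 0
  subj <- list(subject_id = "S1", group = "low")
  resp <- generate_questionnaire(subj, cfg, 4)
  expect_equal(resp$q5_category, "none")
  expect_equal(resp$q6_category, "none")

  expect_equal(count_to_category(10), "2-3 per week")
  expect_equal(count_to_category(0), "none")
  expect_equal(count_to_category(1), "none")          # tie 0/2 -> lower
  expect_equal(count_to_category(7), "1 per week")    # tie 4/10 -> lower
  expect_equal(count_to_category(100), "almost daily")

  cfg$groups$low$questionnaire$item_p <- 1
  resp <- generate_questionnaire(subj, cfg, 4)
  sc <- score_clarke(resp)
  expect_equal(sc$clarke_score, 7L)
  expect_true(sc$reduced_awareness)
})

test_that("default cohorts have the configured group sizes and deterministic output", {
  co <- generate_cohort(cgm_study_config(seed = 3), traces = FALSE)
  expect_equal(as.integer(table(co$subjects$group)[c("low", "high")]),
               c(17L, 17L))
  cq <- generate_cohort(questionnaire_study_config(seed = 3), traces = FALSE)
  expect_equal(as.integer(table(cq$subjects$group)[c("low", "high")]),
               c(35L, 221L))

  small <- noise_free_config(n = 2, days = 1, seed = 9)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  generate_cohort(small, out_dir = d1)
  generate_cohort(small, out_dir = d2)
  for (f in c("subjects.csv", "cgm.csv", "smbg.csv", "clarke.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
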