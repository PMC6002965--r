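# build a trace from below/above minutes: segments of (value, minutes)
pattern_trace <- function(..., start = "2023-03-06 00:00:00") {
  spec <- list(...)
  g <- unlist(lapply(spec, function(s) rep(s[1], s[2] / 5)))
  make_trace(g, start = start)
}

test_that("the 20-min rule and gap merging follow the stated state machine", {
  # 30 min at/below 4.0 -> one episode of 30 min
  tr <- pattern_trace(c(8, 60), c(3.5, 30), c(8, 60))
  ep <- detect_episodes(tr, 4)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_min, 30)
  expect_equal(ep$nadir, 3.5)

  # 15 min below never qualifies
  tr <- pattern_trace(c(8, 60), c(3.5, 15), c(8, 60))
  expect_equal(nrow(detect_episodes(tr, 4)), 0)

  # 25 below / 15 above / 25 below -> one 50-min episode
  tr <- pattern_trace(c(8, 60), c(3.5, 25), c(8, 15), c(3.2, 25), c(8, 60))
  ep <- detect_episodes(tr, 4)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_min, 50)
  expect_equal(ep$nadir, 3.2)

  # a gap of exactly 20 min does not complete the episode either
  tr <- pattern_trace(c(8, 60), c(3.5, 25), c(8, 20), c(3.2, 25), c(8, 60))
  expect_equal(detect_episodes(tr, 4)$duration_min, 50)

  # 25 min above completes it: two separate episodes
  tr <- pattern_trace(c(8, 60), c(3.5, 25), c(8, 25), c(3.2, 25), c(8, 60))
  expect_equal(nrow(detect_episodes(tr, 4)), 2)

  # two sub-20-min runs merged across a short gap qualify jointly
  tr <- pattern_trace(c(8, 60), c(3.5, 15), c(8, 10), c(3.2, 15), c(8, 60))
  ep <- detect_episodes(tr, 4)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_min, 30)

  expect_error(detect_episodes(tr, 0), "threshold")
  tr$glucose[3] <- NA
  expect_error(detect_episodes(tr, 4), "grid")
})

test_that("episodes are assigned to day/night by their start time", {
  # starts 07:55 -> night (boundary 08:00 itself is day)
  tr <- pattern_trace(c(8, 475), c(3.5, 30), c(8, 475))
  expect_equal(detect_episodes(tr, 4)$period, "night")
  tr <- pattern_trace(c(8, 480), c(3.5, 30), c(8, 475))
  expect_equal(detect_episodes(tr, 4)$period, "day")
  # starting exactly at midnight -> night
  tr <- pattern_trace(c(3.5, 30), c(8, 475))
  expect_equal(detect_episodes(tr, 4)$period, "night")

  eps <- data.frame(period = c("day", "night", "night"))
  dn <- day_night_split(eps, exposure_hours = 168)
  expect_equal(dn$count, c(1L, 2L))
  expect_equal(dn$rate_per_week, c(1, 2))
})

test_that("rates and durations are exposure normalised per week", {
  tr <- pattern_trace(c(8, 1000), c(3.5, 40), c(8, 2000), c(3.0, 60),
                      c(8, 6980))   # 7 days total
  ep <- detect_episodes(tr, 4)
  s <- summarize_hypo(ep, 168, thresholds = 4)
  expect_equal(s$count, 2L)
  expect_equal(s$rate_per_week, 2)
  expect_equal(s$duration_min_per_week, 100)
  # linear scaling: same episode count in half the exposure
  s2 <- summarize_hypo(ep[1, ], 84, thresholds = 4)
  expect_equal(s2$rate_per_week, 2)
  expect_error(summarize_hypo(ep, 0), "exposure")
})

test_that("the detector matches the explicit-scan oracle on random traces", {
  set.seed(505)
  for (i in 1:400) {
    n <- sample(10:200, 1)
    g <- random_walk_trace(n, start_value = sample(3:8, 1))
    tr <- make_trace(g)
    for (th in c(4, 3)) {
      got <- detect_episodes(tr, th)
      want <- oracle_episodes(g, th, 5)
      expect_equal(nrow(got), nrow(want),
                   label = sprintf("count, trace %d th %.1f", i, th))
      expect_equal(got$duration_min, want$duration_min,
                   label = sprintf("durations, trace %d th %.1f", i, th))
      expect_equal(got$nadir, want$nadir,
                   label = sprintf("nadirs, trace %d th %.1f", i, th))
    }
  }
})

test_that("episodes are disjoint, each >= 20 min, and durations are monotone in threshold", {
  set.seed(99)
  for (i in 1:30) {
    g <- random_walk_trace(400, start_value = 5)
    tr <- make_trace(g)
    ep4 <- detect_episodes(tr, 4)
    if (nrow(ep4) > 1) {
      o <- order(ep4$start)
      expect_true(all(ep4$end[o][-nrow(ep4)] <= ep4$start[o][-1]))
    }
    expect_true(all(ep4$duration_min >= 20))
    expect_lte(sum(detect_episodes(tr, 3)$duration_min),
               sum(ep4$duration_min))
  }
})

test_that("detection on noise-free traces recovers the injected ground truth exactly", {
  cfg <- noise_free_config(rate_per_week = 5.5, n = 1, days = 7)
  for (seed in 1:10) {
    tr <- generate_trace(list(subject_id = "S", group = "low"), cfg, seed)
    ev <- attr(tr, "events")
    ep <- detect_episodes(tr, 4)
    expect_equal(nrow(ep), nrow(ev), label = paste("seed", seed))
    if (nrow(ev)) {
      expect_equal(ep$nadir, ev$nadir, tolerance = 1e-6)
      # below-threshold time tracks the drawn duration to grid resolution
      expect_lt(max(abs(ep$duration_min - ev$duration_min)), 15)
    }
  }
})

test_that("episodes never span excised QC windows", {
  # a below-threshold stretch crossing a failed window must be split
  g <- c(rep(8, 280), rep(3.5, 16), rep(8, 280), rep(8, 288))
  g <- g[1:576]
  tr <- make_trace(g, start = "2023-03-06 12:00:00")
  seg1 <- make_trace(g[1:288], start = "2023-03-06 12:00:00")
  seg2 <- make_trace(g[289:576], start = "2023-03-07 12:00:00")
  joint <- detect_episodes(tr, 4)
  split <- detect_episodes(list(seg1, seg2), 4)
  expect_equal(nrow(joint), 1)       # 80 min contiguous run
  expect_equal(nrow(split), 2)       # split at the window boundary: 40 + 40
  expect_true(all(split$duration_min >= 20))
})

test_that("high-C-peptide deep hypoglycaemia is night-only under the default model", {
  cfg <- cgm_study_config(seed = 61)
  for (seed in 1:6) {
    tr <- generate_trace(list(subject_id = "H", group = "high"), cfg, seed)
    ep3 <- detect_episodes(tr, 3)
    if (nrow(ep3)) expect_true(all(ep3$period == "night"))
  }
})
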