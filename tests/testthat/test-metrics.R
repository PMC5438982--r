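test_that("a full session segments into one slice per trial", {
  p <- build_protocol("I", pair = "BG", seed = 2)
  sim <- simulate_bee(p, seed = 3)
  slices <- segment_trials(sim$trace, sim$events)
  expect_length(slices, 13)
  expect_equal(vapply(slices, `[[`, 0L, "trial_index"), 1:13)
  expect_equal(vapply(slices, `[[`, "", "phase"),
               c(rep("training", 9), rep("test", 4)))
  # onsets spaced 44 s apart, first at the end of habituation
  onsets <- vapply(slices, `[[`, 0, "onset_t_s")
  expect_equal(onsets, 120 + (0:12) * 44)
  expect_false(any(vapply(slices, `[[`, TRUE, "partial")))
})

test_that("a log without light events yields no slices", {
  tr <- make_trace(rep(5, 100))
  ev <- data.frame(bee_id = "b1", t_s = 0, kind = "phase_mark", side = "none",
                   label = "DARK", intensity_pct = 0, trial_index = 0L,
                   phase = "habituation", stringsAsFactors = FALSE)
  expect_length(segment_trials(tr, ev), 0)
})

test_that("recomputed side assignments agree with the closed-loop log", {
  # the danger light always lands on the half the bee occupied at onset, so
  # the slice's focal-side label must be the protocol's bee-side light
  p <- build_protocol("I", pair = "YB", seed = 14)
  sim <- simulate_bee(p, seed = 15)
  for (s in segment_trials(sim$trace, sim$events)) {
    focal <- if (s$focal_side == "left") s$left else s$right
    expect_equal(focal$label, "Y")
    opp <- if (s$focal_side == "left") s$right else s$left
    expect_equal(opp$label, "B")
  }
})

test_that("preference index follows the occupancy formula and its bounds", {
  # 4 s on the danger (focal) side then 10 s on the safe side
  s <- make_slice(two_phase_positions(5, 20, t_switch = 4))
  pi <- preference_index(s)
  expect_equal(pi$t_focal_s, 4)
  expect_equal(pi$t_nonfocal_s, 10)
  expect_equal(pi$pi, 6 / 14)

  even <- make_slice(two_phase_positions(5, 20, t_switch = 7))
  expect_equal(preference_index(even)$pi, 0)

  allsafe <- make_slice(two_phase_positions(5, 20, t_switch = 0))
  # bee crosses immediately after onset sample: one focal sample remains
  expect_lte(abs(preference_index(allsafe)$pi), 1)

  stay <- make_slice(rep(5, 280))
  expect_equal(preference_index(stay)$pi, -1)
})

test_that("preference index negates under role swap, is invariant under reflection", {
  set.seed(6)
  for (i in 1:20) {
    pos <- pmin(26, pmax(0, cumsum(c(runif(1, 0, 26),
                                     rnorm(279, 0, 0.4)))))
    s <- make_slice(pos)
    a <- preference_index(s)
    # danger role on the opposite side: pi negates exactly
    sw <- s
    sw$focal_side <- setdiff(c("left", "right"), s$focal_side)
    b <- preference_index(sw)
    expect_equal(b$pi, -a$pi)
    # mirroring the chamber mirrors the bee side with it: pi is unchanged
    sr <- make_slice(26 - pos, left = c("G", "100"), right = c("B", "100"))
    expect_equal(preference_index(sr)$pi, a$pi)
    expect_true(abs(a$pi) <= 1)
    expect_equal(a$t_focal_s + a$t_nonfocal_s, 14, tolerance = 1 / 16)
  }
})

test_that("shock counts enumerate the schedule against occupancy", {
  on_all <- make_slice(rep(5, 280))          # never leaves the danger side
  expect_equal(count_shocks(on_all), 44)

  gone <- make_slice(two_phase_positions(5, 20, t_switch = 2))
  expect_equal(count_shocks(gone), 0)        # left before the first pulse

  cross <- make_slice(two_phase_positions(5, 20, t_switch = 8.5))
  expect_equal(count_shocks(cross), 22)      # pulses at 3 + k/4 < 8.5

  # monotone in nested occupancy: staying longer can only add pulses
  counts <- vapply(c(3, 5, 8.5, 11, 14), function(tsw)
    count_shocks(make_slice(two_phase_positions(5, 20, t_switch = tsw))), 0)
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts >= 0 & counts <= 44))
})

test_that("actual counts need an event log and match logged pulses", {
  p <- build_protocol("I", pair = "BG", seed = 2)
  sim <- simulate_bee(p, seed = 3)
  slices <- segment_trials(sim$trace, sim$events)
  s1 <- slices[[1]]
  expect_error(count_shocks(s1, mode = "actual"), "event log")
  logged <- sum(sim$events$kind == "shock_pulse" &
                sim$events$trial_index == 1)
  expect_equal(count_shocks(s1, sim$events, "actual"), logged)
})

test_that("fictive recounts reproduce actual counts on reinforced trials", {
  ds <- simulate_cohort(6, experiment = "I", pair = "BG", reinforced = TRUE,
                        seed = 44)
  for (b in ds$records$bee_id) {
    tr <- ds$traces[ds$traces$bee_id == b, ]
    ev <- ds$events[ds$events$bee_id == b, ]
    for (s in segment_trials(tr, ev)) {
      if (s$phase != "training") next
      expect_equal(count_shocks(s, mode = "fictive"),
                   count_shocks(s, ev, mode = "actual"))
    }
  }
})

test_that("window speed equals distance covered over duration", {
  # stationary
  expect_equal(window_speed((0:80) / 16, rep(7, 81), 0, 3), 0)
  # constant 4 cm/s: 0.25 cm per sample
  pos <- 5 + 0.25 * (0:48)
  expect_equal(window_speed((0:48) / 16, pos, 0, 3), 4)
  # arbitrary walk against a brute-force oracle
  set.seed(9)
  steps <- rnorm(64, 0, 0.3)
  pos <- 13 + cumsum(c(0, steps))
  t <- (0:64) / 16
  expect_equal(window_speed(t, pos, 0, 4), sum(abs(steps)) / 4)
  # reflection about the midline leaves speed unchanged
  expect_equal(window_speed(t, 26 - pos, 0, 4),
               window_speed(t, pos, 0, 4))
  expect_error(window_speed(t, pos, 3, 3), "t0 < t1")
  expect_error(window_speed(t, pos, 0, 100), "cover")
})

test_that("pre/post speeds bracket light onset symmetrically", {
  s <- make_slice(5 + 0.07 * (0:279))  # constant walk through onset
  sp <- pre_post_speed(s)
  expect_equal(sp$speed_pre_cm_s, sp$speed_post_cm_s, tolerance = 1e-9)
  expect_equal(sp$speed_post_cm_s, 0.07 * 16)
})

test_that("speed change compares first test against first training trial", {
  m <- data.frame(
    bee_id = "b", trial_index = c(1, 2, 10),
    phase = c("training", "training", "test"),
    speed_pre_cm_s = c(4.0, 4.4, 4.1),
    speed_post_cm_s = c(3.8, 4.5, 5.2))
  d <- delta_speed(m)
  expect_equal(d$delta_post, 1.4)
  expect_equal(d$pct_post, 100 * 1.4 / 3.8, tolerance = 1e-9)  # ~36.8%
  expect_equal(d$delta_pre, 0.1, tolerance = 1e-9)
  same <- m; same$speed_post_cm_s <- 4; same$speed_pre_cm_s <- 4
  expect_equal(delta_speed(same)$delta_post, 0)
  expect_error(delta_speed(m[m$phase == "training", ]), "training and.*test")
})

test_that("exclusion uses a strict 2 cm/s cut on mean test-trial speed", {
  bs <- data.frame(bee_id = c("slow", "edge", "ok"),
                   mean_test_speed_cm_s = c(1.25, 2.0, 4.1),
                   excluded = NA)
  out <- apply_exclusion(bs)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))  # exactly 2.0 is retained
  bs$mean_test_speed_cm_s[2] <- NA
  expect_error(apply_exclusion(bs), "without test trials")
})

test_that("cohort summaries give mean and sd/sqrt(n) per trial cell", {
  m <- data.frame(
    bee_id = rep(c("a", "b"), each = 1), trial_index = 1L,
    phase = "training", pi = c(0.2, 0.4), shocks = c(10, 20),
    speed_pre_cm_s = c(4, 4), speed_post_cm_s = c(5, 7))
  bees <- data.frame(bee_id = c("a", "b"), paradigm = "reinforced",
                     protocol_name = "expI-BG", excluded = FALSE)
  g <- summarize_cohort(m, bees)
  expect_equal(g$mean_pi, 0.3)
  expect_equal(g$sem_pi, 0.1, tolerance = 1e-9)
  expect_equal(g$mean_shocks, 15)
  expect_equal(g$n, 2)
  solo <- summarize_cohort(m[1, ], bees[1, ])
  expect_equal(solo$mean_pi, 0.2)
  expect_true(is.na(solo$sem_pi))
  allout <- bees; allout$excluded <- TRUE
  expect_error(summarize_cohort(m, allout), "no analyzable bees")
})
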