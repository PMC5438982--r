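# Hand-built traces, event logs and slices used across the metric tests.

FS <- 16

make_trace <- function(positions, bee = "b1", t0 = 0) {
  data.frame(bee_id = bee,
             t_s = t0 + (seq_along(positions) - 1) / FS,
             position_cm = positions,
             sensor_index = pmin(26L, pmax(1L, ceiling(positions))),
             stringsAsFactors = FALSE)
}

make_trial_events <- function(onset, left = c("B", "100"), right = c("G", "100"),
                              trial = 1L, phase = "training", bee = "b1") {
  rows <- list()
  add <- function(t, kind, side, lab, int)
    rows[[length(rows) + 1]] <<- data.frame(
      bee_id = bee, t_s = t, kind = kind, side = side, label = lab,
      intensity_pct = as.numeric(int), trial_index = trial, phase = phase,
      stringsAsFactors = FALSE)
  if (as.numeric(left[2]) > 0) {
    add(onset, "light_on", "left", left[1], left[2])
    add(onset + 14, "light_off", "left", left[1], left[2])
  }
  if (as.numeric(right[2]) > 0) {
    add(onset, "light_on", "right", right[1], right[2])
    add(onset + 14, "light_off", "right", right[1], right[2])
  }
  do.call(rbind, rows)
}

# one-trial slice from a hand-built position vector spanning [0, onset + 14)+
make_slice <- function(positions, onset = 3, ...) {
  tr <- make_trace(positions)
  ev <- make_trial_events(onset, ...)
  segment_trials(tr, ev)[[1]]
}

# positions for a bee sitting at x1 for the first `t_switch` s of the
# stimulus then at x2 (plus a 3 s pre period at x1)
two_phase_positions <- function(x1, x2, onset = 3, t_switch = 4,
                                total_s = 17.5) {
  n <- round(total_s * FS)
  t <- (seq_len(n) - 1) / FS
  ifelse(t < onset + t_switch, x1, x2)
}

expect_same_dataset <- function(a, b) {
  expect_equal(a$traces, b$traces, tolerance = 1e-9)
  expect_equal(a$events, b$events, tolerance = 1e-9)
  expect_equal(a$records, b$records)
}
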