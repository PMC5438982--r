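test_that("experiment I builds 9 shocked training plus 4 clean test trials", {
  p <- build_protocol("I", pair = "BG", reinforced = TRUE, seed = 1)
  phases <- vapply(p$trials, `[[`, "", "phase")
  expect_equal(sum(phases == "training"), 9)
  expect_equal(sum(phases == "test"), 4)
  expect_true(all(vapply(p$trials[phases == "training"], `[[`, TRUE,
                         "shock_on_bee_side")))
  expect_false(any(vapply(p$trials[phases == "test"], `[[`, TRUE,
                          "shock_on_bee_side")))
  expect_true(all(vapply(p$trials, function(t) t$bee_side_light$label, "")
                  [phases == "training"] == "B"))
  u <- build_protocol("I", pair = "GY", reinforced = FALSE, seed = 1)
  expect_false(any(vapply(u$trials, `[[`, TRUE, "shock_on_bee_side")))
  expect_equal(u$trials[[1]]$bee_side_light$label, "G")
  expect_equal(u$trials[[1]]$opposite_side_light$label, "Y")
})

test_that("experiment II test battery probes the six trained/untrained pairings", {
  p <- build_protocol("II", pair = "BG", seed = 7)
  tests <- p$trials[10:15]
  combos <- vapply(tests, function(t)
    paste(t$bee_side_light$label, t$opposite_side_light$label), "")
  # single-color triplet: each light vs darkness; dual-color triplet:
  # danger vs untrained, safe vs untrained, passive avoidance (safe|danger)
  expect_setequal(combos, c("B DARK", "G DARK", "Y DARK", "B Y", "G Y", "G B"))
  first3 <- combos[1:3]
  expect_true(all(grepl("DARK", first3)) || !any(grepl("DARK", first3)))
  expect_false(any(vapply(tests, `[[`, TRUE, "shock_on_bee_side")))
})

test_that("experiment II triplet order is seeded and both orders occur", {
  p1 <- build_protocol("II", pair = "BG", seed = 7)
  p2 <- build_protocol("II", pair = "BG", seed = 7)
  expect_identical(vapply(p1$trials, function(t) t$bee_side_light$label, ""),
                   vapply(p2$trials, function(t) t$bee_side_light$label, ""))
  single_first <- vapply(1:40, function(s) {
    p <- build_protocol("II", pair = "BG", seed = s)
    all(vapply(p$trials[10:12], function(t)
      t$opposite_side_light$label == "DARK", TRUE))
  }, TRUE)
  expect_gt(sum(single_first), 5)
  expect_gt(sum(!single_first), 5)
  pf <- build_protocol("II", pair = "BG", seed = 7, single_color_first = TRUE)
  expect_true(all(vapply(pf$trials[10:12], function(t)
    t$opposite_side_light$label == "DARK", TRUE)))
})

test_that("experiment III sweeps 0-100% twice per series with reciprocal presentation", {
  p <- build_protocol("III", ref = "Y", test = "G", seed = 3)
  expect_length(p$trials, 44)
  expect_false(p$reinforced)
  expect_true(all(vapply(p$trials, `[[`, "", "phase") == "preference"))
  # odd trials: reference (100%) on the bee side; even: reversed
  odd <- p$trials[seq(1, 44, 2)]; even <- p$trials[seq(2, 44, 2)]
  expect_true(all(vapply(odd, function(t) t$bee_side_light$label, "") == "Y"))
  expect_true(all(vapply(odd, function(t) t$bee_side_light$intensity_pct, 0) == 100))
  expect_true(all(vapply(even, function(t) t$opposite_side_light$label, "") == "Y"))
  test_int <- vapply(odd, function(t) t$opposite_side_light$intensity_pct, 0)
  expect_setequal(unique(test_int), seq(0, 100, 10))
  expect_equal(as.vector(table(test_int)), rep(2L, 11))  # two series
  # one series ascends, the other descends
  expect_true(all(diff(test_int[1:11]) == 10) || all(diff(test_int[1:11]) == -10))
  expect_equal(test_int[12:22], rev(test_int[1:11]))
  expect_error(build_protocol("III", ref = "G", test = "G"), "distinct")
})

test_that("experiment IV prepends a preference probe and equates green intensity", {
  p <- build_protocol("IV", pair = "GB", seed = 1)
  expect_equal(p$trials[[1]]$phase, "preference")
  expect_false(p$trials[[1]]$shock_on_bee_side)
  expect_equal(p$trials[[1]]$bee_side_light$intensity_pct, 62)  # G vs B
  expect_equal(p$trials[[2]]$phase, "training")
  expect_length(p$trials, 14)
  p2 <- build_protocol("IV", pair = "YG", seed = 1)
  expect_equal(p2$trials[[1]]$opposite_side_light$label, "G")
  expect_equal(p2$trials[[1]]$opposite_side_light$intensity_pct, 46)  # G vs Y
  expect_equal(p2$trials[[1]]$bee_side_light$intensity_pct, 100)
  expect_error(build_protocol("IV", pair = "BY"), "green")
})

test_that("protocol audits reject malformed schedules and unknown configs", {
  expect_error(build_protocol("I", pair = "BB"), "unknown color pair")
  expect_error(build_protocol("V"))
  p <- build_protocol("I", pair = "BG", seed = 1)
  expect_silent(validate_protocol(p))
  expect_equal(protocol_duration_s(p), 120 + 13 * 44)
  broken <- p
  broken$trials <- p$trials[1:5]
  expect_error(validate_protocol(broken), "expects")
})

test_that("protocols survive a YAML round-trip", {
  p <- build_protocol("II", pair = "YB", seed = 11)
  f <- tempfile(fileext = ".yaml")
  write_protocol(p, f)
  q <- read_protocol(f)
  expect_equal(q$name, p$name)
  expect_equal(length(q$trials), length(p$trials))
  for (k in seq_along(p$trials)) {
    expect_equal(q$trials[[k]]$bee_side_light$label,
                 p$trials[[k]]$bee_side_light$label)
    expect_equal(q$trials[[k]]$shock_on_bee_side,
                 p$trials[[k]]$shock_on_bee_side)
  }
  expect_equal(q$chamber$length_cm, p$chamber$length_cm)
})
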