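#' Single trial specification
#'
#' One trial of the paradigm: a 14 s simultaneous presentation of two light
#' fields (one per chamber half) within a 44 s onset-to-onset window, with an
#' optional shock train on the bee side. The side each stimulus lands on is
#' resolved at run time from the bee's position (\code{\link{resolve_sides}}).
#'
#' @param index Trial number within the protocol (1-based; habituation is not
#'   a trial).
#' @param phase One of \code{"habituation"}, \code{"training"}, \code{"test"},
#'   \code{"preference"}.
#' @param bee_side_light \code{\link{light_source}} presented on the chamber
#'   half containing the bee at onset. In training trials this is the danger
#'   light.
#' @param opposite_side_light \code{\link{light_source}} presented on the
#'   other half; darkness is an explicit \code{light_source("DARK")}.
#' @param shock_on_bee_side Whether the trial delivers shocks on the bee side.
#' @param shock A \code{\link{shock_spec}} or \code{NULL}.
#' @param stimulus_duration_s,onset_to_onset_s Stimulus and trial spacing (s).
#' @return An object of class \code{trial_spec}.
#' @export
trial_spec <- function(index, phase, bee_side_light,
                       opposite_side_light = light_source("DARK"),
                       shock_on_bee_side = FALSE, shock = NULL,
                       stimulus_duration_s = 14, onset_to_onset_s = 44) {
  phase <- match.arg(phase, c("habituation", "training", "test", "preference"))
  stopifnot(inherits(bee_side_light, "light_source"),
            inherits(opposite_side_light, "light_source"),
            stimulus_duration_s <= onset_to_onset_s)
  if (shock_on_bee_side && is.null(shock))
    stop("shock_on_bee_side = TRUE requires a shock_spec")
  if (!is.null(shock)) stopifnot(inherits(shock, "shock_spec"))
  if (phase == "habituation")
    stop("habituation is a protocol-level dark period, not a trial")
  structure(list(
    index = as.integer(index), phase = phase,
    stimulus_duration_s = stimulus_duration_s,
    onset_to_onset_s = onset_to_onset_s,
    bee_side_light = bee_side_light,
    opposite_side_light = opposite_side_light,
    shock_on_bee_side = isTRUE(shock_on_bee_side),
    shock = shock
  ), class = "trial_spec")
}

.pair_colors <- function(pair) {
  pairs <- c("BG", "GB", "BY", "YB", "YG", "GY")
  if (!pair %in% pairs)
    stop("unknown color pair '", pair, "'; expected one of ",
         paste(pairs, collapse = ", "))
  list(plus = substr(pair, 1, 1), minus = substr(pair, 2, 2))
}

#' Build a full conditioning protocol
#'
#' Constructs the trial schedule of one of the four experiments of the
#' paradigm:
#' \describe{
#'   \item{I}{Differential aversive conditioning at maximal intensities:
#'     9 training trials (danger light shocked if \code{reinforced}) followed
#'     by 4 unreinforced test trials in the same color combination.}
#'   \item{II}{As I, but the test phase is a six-trial battery probing what
#'     was learned: each of the three lights against darkness (single-color
#'     triplet), plus the danger light vs the untrained light, the safe light
#'     vs the untrained light, and a passive-avoidance trial with the safe
#'     light on the bee side and the danger light opposite (dual-color
#'     triplet). Half of the bees receive the single-color triplet first;
#'     the order within each triplet is pseudorandomized from \code{seed}.}
#'   \item{III}{Unreinforced intensity-preference series: a reference light
#'     held at 100\% against a test light swept 0--100\% in 10\% steps, two
#'     series per bee (one increasing, one decreasing, order seeded), each
#'     intensity presented twice in a reciprocal fashion (reference on the
#'     bee side, then on the opposite side): 44 trials.}
#'   \item{IV}{As I, with intensities equated for innate preference: the
#'     green light runs at 62\% against blue and 46\% against yellow (both at
#'     100\%), and a single unreinforced preference trial precedes training.}
#' }
#'
#' @param experiment \code{"I"}, \code{"II"}, \code{"III"} or \code{"IV"}.
#' @param pair Two-letter color pair, danger light first (e.g. \code{"BG"}
#'   = blue shocked, green safe). Experiments I, II, IV.
#' @param ref,test Reference and test light labels for experiment III.
#' @param reinforced Whether shocks are armed (experiment III is always
#'   unreinforced).
#' @param seed Seed for the protocol's pseudorandomized orderings
#'   (experiment II triplets, experiment III series direction).
#' @param single_color_first For experiment II: \code{TRUE}/\code{FALSE} to
#'   force the triplet order, or \code{NULL} (default) to draw it from
#'   \code{seed}.
#' @param habituation_s Initial dark habituation period (s).
#' @param chamber A \code{\link{chamber_spec}}.
#' @param shock A \code{\link{shock_spec}} used for reinforced trials.
#' @return An object of class \code{apis_protocol}: a list with fields
#'   \code{name}, \code{experiment}, \code{reinforced}, \code{habituation_s},
#'   \code{chamber}, \code{shock}, and \code{trials} (list of
#'   \code{\link{trial_spec}}).
#' @export
build_protocol <- function(experiment = c("I", "II", "III", "IV"),
                           pair = "BG", ref = "B", test = "G",
                           reinforced = TRUE, seed = 1L,
                           single_color_first = NULL,
                           habituation_s = 120,
                           chamber = chamber_spec(),
                           shock = shock_spec()) {
  experiment <- match.arg(experiment)
  # pseudorandomized orderings drawn once from the protocol's own seed
  draws <- local_seed(seed, list(
    perm_single = sample.int(3), perm_dual = sample.int(3),
    single_first = runif(1) < 0.5, increasing_first = runif(1) < 0.5))
  mk_training <- function(idx, plus, minus, int_plus = 100, int_minus = 100) {
    lapply(idx, function(i) trial_spec(
      i, "training",
      bee_side_light = light_source(plus, int_plus),
      opposite_side_light = light_source(minus, int_minus),
      shock_on_bee_side = reinforced,
      shock = if (reinforced) shock else NULL))
  }

  if (experiment %in% c("I", "II")) {
    pc <- .pair_colors(pair)
    trials <- mk_training(1:9, pc$plus, pc$minus)
    if (experiment == "I") {
      tests <- lapply(10:13, function(i) trial_spec(
        i, "test", light_source(pc$plus), light_source(pc$minus)))
    } else {
      lambda0 <- setdiff(c("B", "G", "Y"), c(pc$plus, pc$minus))
      single <- list(  # each light on the bee side against darkness
        list(bee = pc$plus, opp = "DARK"),
        list(bee = pc$minus, opp = "DARK"),
        list(bee = lambda0, opp = "DARK"))
      dual <- list(    # trained lights vs the untrained light; passive avoidance
        list(bee = pc$plus, opp = lambda0),
        list(bee = pc$minus, opp = lambda0),
        list(bee = pc$minus, opp = pc$plus))
      single <- single[draws$perm_single]
      dual <- dual[draws$perm_dual]
      if (is.null(single_color_first)) single_color_first <- draws$single_first
      battery <- if (single_color_first) c(single, dual) else c(dual, single)
      tests <- lapply(seq_along(battery), function(k) trial_spec(
        9L + k, "test",
        light_source(battery[[k]]$bee),
        light_source(battery[[k]]$opp)))
    }
    trials <- c(trials, tests)
    name <- sprintf("exp%s-%s", experiment, pair)
  } else if (experiment == "III") {
    ref <- match.arg(ref, c("B", "G", "Y"))
    test <- match.arg(test, c("B", "G", "Y"))
    if (ref == test) stop("experiment III needs distinct ref and test lights")
    reinforced <- FALSE
    levels_up <- seq(0, 100, by = 10)
    series <- if (draws$increasing_first) list(levels_up, rev(levels_up))
              else list(rev(levels_up), levels_up)
    trials <- list(); i <- 0L
    for (lv in unlist(series)) {
      # reciprocal presentation: reference on the bee side first, then opposite
      i <- i + 1L
      trials[[i]] <- trial_spec(i, "preference",
                                light_source(ref, 100), light_source(test, lv))
      i <- i + 1L
      trials[[i]] <- trial_spec(i, "preference",
                                light_source(test, lv), light_source(ref, 100))
    }
    name <- sprintf("expIII-ref%s-test%s", ref, test)
  } else { # IV
    pc <- .pair_colors(pair)
    if (!"G" %in% c(pc$plus, pc$minus))
      stop("experiment IV pairs green with blue or yellow (pairs BG, GB, YG, GY)")
    other <- setdiff(c(pc$plus, pc$minus), "G")
    g_int <- if (other == "B") 62 else 46
    int_of <- function(lab) if (lab == "G") g_int else 100
    trials <- list(trial_spec(1L, "preference",
                              light_source(pc$plus, int_of(pc$plus)),
                              light_source(pc$minus, int_of(pc$minus))))
    trials <- c(trials,
                mk_training(2:10, pc$plus, pc$minus,
                            int_of(pc$plus), int_of(pc$minus)),
                lapply(11:14, function(i) trial_spec(
                  i, "test",
                  light_source(pc$plus, int_of(pc$plus)),
                  light_source(pc$minus, int_of(pc$minus)))))
    name <- sprintf("expIV-%s", pair)
  }

  p <- structure(list(
    name = name, experiment = experiment, reinforced = reinforced,
    habituation_s = habituation_s, chamber = chamber, shock = shock,
    seed = as.integer(seed), trials = trials
  ), class = "apis_protocol")
  validate_protocol(p)
  p
}

#' Audit a protocol against the paradigm's structural invariants
#'
#' Checks trial counts per phase for the experiment, the 44 s onset-to-onset
#' spacing, that habituation carries no trial, and that every reinforced
#' trial has a consistent shock specification.
#'
#' @param protocol An \code{apis_protocol}.
#' @return The protocol, invisibly; stops on violation.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "apis_protocol"))
  tr <- protocol$trials
  phases <- vapply(tr, `[[`, "", "phase")
  idx <- vapply(tr, `[[`, 0L, "index")
  if (!identical(idx, seq_along(tr)))
    stop("trial indices must be consecutive from 1")
  counts <- table(factor(phases, c("preference", "training", "test")))
  want <- switch(protocol$experiment,
                 I = c(preference = 0, training = 9, test = 4),
                 II = c(preference = 0, training = 9, test = 6),
                 III = c(preference = 44, training = 0, test = 0),
                 IV = c(preference = 1, training = 9, test = 4))
  if (!all(counts == want))
    stop(sprintf("experiment %s expects %s trials, found %s",
                 protocol$experiment,
                 paste(want, collapse = "/"), paste(counts, collapse = "/")))
  for (t in tr) {
    if (t$onset_to_onset_s != 44 || t$stimulus_duration_s != 14)
      stop("non-standard trial timing in trial ", t$index)
    if (t$shock_on_bee_side && !protocol$reinforced)
      stop("unreinforced protocol contains a shocked trial")
    if (t$phase %in% c("test", "preference") && t$shock_on_bee_side)
      stop("test/preference trials must be unreinforced")
  }
  invisible(protocol)
}

#' @export
print.apis_protocol <- function(x, ...) {
  phases <- vapply(x$trials, `[[`, "", "phase")
  cat(sprintf("Protocol %s (%s): %d trials [%s], %s, habituation %g s\n",
              x$name, x$experiment, length(x$trials),
              paste(sprintf("%s x%d", names(table(phases)), table(phases)),
                    collapse = ", "),
              if (x$reinforced) "reinforced" else "unreinforced",
              x$habituation_s))
  invisible(x)
}

#' Protocol session duration in seconds
#' @param protocol An \code{apis_protocol}.
#' @return Total session duration (habituation plus one 44 s window per trial).
#' @export
protocol_duration_s <- function(protocol) {
  protocol$habituation_s +
    sum(vapply(protocol$trials, `[[`, 0, "onset_to_onset_s"))
}

#' Serialize / deserialize a protocol
#'
#' Protocols are written as a human-readable YAML document holding the
#' chamber, shock and trial list, so the exact stimulus schedule a cohort ran
#' can be archived next to its logs.
#'
#' @param protocol An \code{apis_protocol}.
#' @param path File to write to / read from.
#' @return \code{read_protocol} returns the reconstructed
#'   \code{apis_protocol}; \code{write_protocol} returns \code{path},
#'   invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "apis_protocol"))
  doc <- list(
    schema = "apisim-protocol/1",
    name = protocol$name, experiment = protocol$experiment,
    reinforced = protocol$reinforced, habituation_s = protocol$habituation_s,
    seed = protocol$seed,
    chamber = unclass(protocol$chamber)[c("length_cm", "n_sensors", "sample_rate_hz")],
    shock = unclass(protocol$shock),
    trials = lapply(protocol$trials, function(t) list(
      index = t$index, phase = t$phase,
      stimulus_duration_s = t$stimulus_duration_s,
      onset_to_onset_s = t$onset_to_onset_s,
      bee_side = list(label = t$bee_side_light$label,
                      intensity_pct = t$bee_side_light$intensity_pct),
      opposite_side = list(label = t$opposite_side_light$label,
                           intensity_pct = t$opposite_side_light$intensity_pct),
      shock_on_bee_side = t$shock_on_bee_side)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "apisim-protocol/1"))
    stop("unrecognized protocol schema: ", doc$schema)
  shock <- do.call(shock_spec, doc$shock)
  trials <- lapply(doc$trials, function(t) trial_spec(
    t$index, t$phase,
    light_source(t$bee_side$label, t$bee_side$intensity_pct),
    light_source(t$opposite_side$label, t$opposite_side$intensity_pct),
    shock_on_bee_side = t$shock_on_bee_side,
    shock = if (t$shock_on_bee_side) shock else NULL,
    stimulus_duration_s = t$stimulus_duration_s,
    onset_to_onset_s = t$onset_to_onset_s))
  p <- structure(list(
    name = doc$name, experiment = doc$experiment, reinforced = doc$reinforced,
    habituation_s = doc$habituation_s,
    chamber = do.call(chamber_spec, doc$chamber),
    shock = shock, seed = doc$seed, trials = trials
  ), class = "apis_protocol")
  validate_protocol(p)
  p
}
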