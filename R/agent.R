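#' Default phototactic drive
#'
#' Attractiveness of a light as a function of LED label and relative
#' intensity: a saturating (half-saturation \code{half_sat} percent) drive
#' scaled by a wavelength-dependent gain. The default gains encode the
#' assay's innate ordering -- green is the most attractive light, blue
#' slightly more attractive than yellow -- with all three strongly
#' phototactic at full intensity; darkness has zero drive.
#'
#' @param label LED label (\code{"B"}, \code{"G"}, \code{"Y"}, \code{"DARK"}).
#' @param intensity_pct Relative intensity in percent.
#' @param gains Named gains per LED label.
#' @param half_sat Intensity (percent) at half-maximal drive.
#' @return Non-negative scalar drive.
#' @export
default_attractiveness <- function(label, intensity_pct,
                                   gains = c(B = 1.0, G = 1.15, Y = 0.9),
                                   half_sat = 30) {
  if (label == "DARK" || intensity_pct <= 0) return(0)
  unname(gains[label]) * intensity_pct / (intensity_pct + half_sat)
}

#' Behavioral parameters of the simulated bee
#'
#' Parameters of the agent-based walking-bee model: a persistent 1-D random
#' walk with phototactic bias, shock-triggered escape/arousal, per-pulse
#' associative acquisition of aversion for the shocked light, and a
#' wavelength-dependent safety prior that can block the behavioral
#' expression of that aversion (the model's account of the green-light
#' learning asymmetry).
#'
#' @param base_speed_cm_s Mean step speed (cm/s).
#' @param speed_sd Per-sample speed standard deviation (cm/s).
#' @param persistence Probability of keeping the walking direction per 1/16 s
#'   sample in the absence of any utility difference. The default (0.98)
#'   gives straight runs of about 3 s / 12 cm, the end-to-end shuttling bees
#'   show in the chamber; much lower values make the walk too diffusive to
#'   redistribute across the midline within a 14 s trial.
#' @param attractiveness Function \code{(label, intensity_pct) -> a >= 0}
#'   giving the phototactic drive of a stimulus.
#' @param learning_rate_alpha Per-delivered-pulse acquisition rate in [0, 1].
#' @param aversion_max Asymptote of learned aversion V.
#' @param safety_prior Named vector (per LED label) subtracted from acquired
#'   aversion before it is expressed as avoidance; a value at or above
#'   \code{aversion_max} makes the light's aversion unexpressable. Default:
#'   green is fully protected, blue and yellow not at all.
#' @param shock_speed_factor Multiplicative speed boost from the first
#'   received pulse until light offset.
#' @param anticipation_rate Per-delivered-pulse acquisition rate of the fear
#'   (arousal) trace F in [0, 1]. F saturates much faster than place
#'   aversion, mirroring the assay's rapid and protocol-independent
#'   emergence of shock anticipation.
#' @param anticipation_gain Light-onset arousal: while lights are on, speed
#'   is multiplied by \code{1 + anticipation_gain * max(F)} over the lit
#'   labels. F is independent of the safety prior, so a bee anticipates
#'   shocks signalled by a light it never learns to place-avoid.
#' @param crossing_gain Scales how the utility difference between the two
#'   chamber halves biases the direction-flip probability.
#' @param quantize Whether emitted positions are snapped to sensor centers
#'   (the discretization the real device imposes).
#' @return An object of class \code{agent_params}.
#' @export
agent_params <- function(base_speed_cm_s = 4, speed_sd = 1, persistence = 0.98,
                         attractiveness = default_attractiveness,
                         learning_rate_alpha = 0.002, aversion_max = 2,
                         safety_prior = c(B = 0, G = 2, Y = 0),
                         shock_speed_factor = 1.5, anticipation_rate = 0.06,
                         anticipation_gain = 0.35,
                         crossing_gain = 0.05, quantize = TRUE) {
  stopifnot(base_speed_cm_s > 0, speed_sd >= 0,
            persistence >= 0, persistence <= 1,
            learning_rate_alpha >= 0, learning_rate_alpha <= 1,
            aversion_max >= 0, shock_speed_factor > 0,
            anticipation_rate >= 0, anticipation_rate <= 1,
            anticipation_gain >= 0,
            is.function(attractiveness),
            all(c("B", "G", "Y") %in% names(safety_prior)),
            all(safety_prior >= 0))
  structure(list(
    base_speed_cm_s = base_speed_cm_s, speed_sd = speed_sd,
    persistence = persistence, attractiveness = attractiveness,
    learning_rate_alpha = learning_rate_alpha, aversion_max = aversion_max,
    safety_prior = safety_prior, shock_speed_factor = shock_speed_factor,
    anticipation_rate = anticipation_rate,
    anticipation_gain = anticipation_gain, crossing_gain = crossing_gain,
    quantize = isTRUE(quantize)
  ), class = "agent_params")
}

#' Agent state
#'
#' @param position_cm Position in the chamber.
#' @param direction Walking direction, -1 (leftward) or +1 (rightward).
#' @param learned_aversion Named vector of acquired aversion V per LED label.
#' @param fear Named vector of the fast arousal trace F per LED label.
#' @param trial_index,time_s Bookkeeping.
#' @return An object of class \code{agent_state}.
#' @export
agent_state <- function(position_cm, direction = 1L,
                        learned_aversion = c(B = 0, G = 0, Y = 0),
                        fear = c(B = 0, G = 0, Y = 0),
                        trial_index = 0L, time_s = 0) {
  stopifnot(direction %in% c(-1L, 1L),
            all(c("B", "G", "Y") %in% names(learned_aversion)),
            all(c("B", "G", "Y") %in% names(fear)))
  structure(list(position_cm = position_cm, direction = as.integer(direction),
                 learned_aversion = learned_aversion, fear = fear,
                 trial_index = as.integer(trial_index), time_s = time_s),
            class = "agent_state")
}

# Expressed side utility: phototactic drive minus safety-gated aversion.
.side_utility <- function(stim, V, params) {
  if (stim$label == "DARK") return(0)
  a <- params$attractiveness(stim$label, stim$intensity_pct)
  a - max(0, V[[stim$label]] - params$safety_prior[[stim$label]])
}

#' Advance the agent by one sample
#'
#' One 1/16 s update of the walking-bee model. If a shock pulse is being
#' received, acquired aversion of the light on the bee's current side is
#' incremented by \code{alpha * (V_max - V)} and the step speed is boosted by
#' \code{shock_speed_factor}. The walking direction flips with probability
#' \code{(1 - persistence) + crossing_gain * (U_behind - U_ahead)} (clipped
#' to [0, 1]), where \code{U_ahead} is the expressed utility of the chamber
#' half the bee is walking toward; displacement is \code{speed * direction /
#' sample_rate} with reflecting boundaries.
#'
#' This is the reference single-step form of the update;
#' \code{\link{simulate_bee}} runs the same dynamics over a whole protocol.
#' Uses the current RNG stream.
#'
#' @param state An \code{\link{agent_state}}.
#' @param side_stimuli A \code{\link{resolve_sides}} assignment (what is lit
#'   on each half); pass a dark assignment for inter-trial periods.
#' @param pulse_active Whether a shock pulse is delivered to the bee this
#'   sample.
#' @param params An \code{\link{agent_params}}.
#' @param chamber A \code{\link{chamber_spec}}.
#' @return The updated \code{agent_state}.
#' @export
step_agent <- function(state, side_stimuli, pulse_active, params,
                       chamber = chamber_spec()) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "agent_params"))
  V <- state$learned_aversion
  Fv <- state$fear
  dt <- 1 / chamber$sample_rate_hz
  here <- chamber_side(state$position_cm, chamber)
  if (isTRUE(pulse_active)) {
    lab <- if (here == "left") side_stimuli$left_stimulus$label
           else side_stimuli$right_stimulus$label
    if (lab != "DARK") {
      V[[lab]] <- V[[lab]] +
        params$learning_rate_alpha * (params$aversion_max - V[[lab]])
      Fv[[lab]] <- Fv[[lab]] + params$anticipation_rate * (1 - Fv[[lab]])
    }
  }
  u_left <- .side_utility(side_stimuli$left_stimulus, V, params)
  u_right <- .side_utility(side_stimuli$right_stimulus, V, params)
  ahead <- if (state$direction > 0) u_right else u_left
  behind <- if (state$direction > 0) u_left else u_right
  p_flip <- min(1, max(0, (1 - params$persistence) +
                            params$crossing_gain * (behind - ahead)))
  dir <- if (stats::runif(1) < p_flip) -state$direction else state$direction
  speed <- max(0, stats::rnorm(1, params$base_speed_cm_s, params$speed_sd))
  lit <- c(if (side_stimuli$left_stimulus$intensity_pct > 0)
             side_stimuli$left_stimulus$label,
           if (side_stimuli$right_stimulus$intensity_pct > 0)
             side_stimuli$right_stimulus$label)
  if (length(lit))
    speed <- speed * (1 + params$anticipation_gain * max(Fv[lit]))
  if (isTRUE(pulse_active)) speed <- speed * params$shock_speed_factor
  pos <- state$position_cm + dir * speed * dt
  if (pos < 0) { pos <- -pos; dir <- 1L }
  if (pos > chamber$length_cm) { pos <- 2 * chamber$length_cm - pos; dir <- -1L }
  agent_state(pos, dir, V, Fv, state$trial_index, state$time_s + dt)
}

# sensor index (1-based) and sensor-center position for a continuous position
.sensor_index <- function(pos, chamber) {
  pmin(chamber$n_sensors, pmax(1L, ceiling(pos / chamber$pitch_cm)))
}

#' Simulate one bee through a protocol
#'
#' Runs the walking-bee model through a full protocol session (habituation
#' plus every 44 s trial window) under the closed-loop rule: at each trial
#' onset the bee-side stimulus is presented on the chamber half containing
#' the bee, and in reinforced trials scheduled shock pulses are delivered
#' only when the bee occupies the shocked half at the pulse time (judged on
#' the emitted, sensor-quantized position, exactly as an offline reanalysis
#' of the trace would).
#'
#' @param protocol An \code{apis_protocol}.
#' @param params An \code{\link{agent_params}}.
#' @param seed Integer seed; the full session is reproducible from it.
#' @param bee_id Identifier written into the logs.
#' @return A list with \code{trace} (data.frame: bee_id, t_s, position_cm,
#'   sensor_index) and \code{events} (data.frame: bee_id, t_s, kind, side,
#'   label, intensity_pct, trial_index, phase).
#' @export
simulate_bee <- function(protocol, params = agent_params(), seed = 1L,
                         bee_id = "bee001") {
  stopifnot(inherits(protocol, "apis_protocol"),
            inherits(params, "agent_params"))
  local_seed(seed, .simulate_bee_impl(protocol, params, bee_id))
}

.simulate_bee_impl <- function(protocol, params, bee_id) {
  ch <- protocol$chamber
  fs <- ch$sample_rate_hz
  dt <- 1 / fs
  L <- ch$length_cm
  nT <- length(protocol$trials)
  hab_n <- round(protocol$habituation_s * fs)
  win_n <- round(44 * fs)
  stim_n <- round(14 * fs)
  N <- hab_n + nT * win_n
  tvec <- (seq_len(N) - 1) * dt

  # per-sample trial context
  trial_id <- integer(N)
  onset_i <- hab_n + (seq_len(nT) - 1L) * win_n + 1L
  for (k in seq_len(nT))
    trial_id[onset_i[k]:(onset_i[k] + stim_n - 1L)] <- k
  pulse_rel <- round(shock_pulse_times(protocol$shock) * fs) # samples after onset
  is_pulse <- logical(N)
  for (k in seq_len(nT)) {
    tr <- protocol$trials[[k]]
    if (tr$shock_on_bee_side) is_pulse[onset_i[k] + pulse_rel] <- TRUE
  }

  # pre-drawn randomness
  pos <- stats::runif(1) * L
  dir <- if (stats::runif(1) < 0.5) -1L else 1L
  flips <- stats::runif(N)
  speeds <- pmax(0, stats::rnorm(N, params$base_speed_cm_s, params$speed_sd))

  V <- c(B = 0, G = 0, Y = 0)
  Fv <- c(B = 0, G = 0, Y = 0)
  s_prior <- params$safety_prior
  alpha <- params$learning_rate_alpha
  vmax <- params$aversion_max
  gain <- params$crossing_gain
  flip0 <- 1 - params$persistence

  posq <- numeric(N)
  sensor <- integer(N)

  # event buffers
  ev_cap <- 1L + nT * (5L + length(pulse_rel))
  ev_t <- numeric(ev_cap); ev_kind <- character(ev_cap)
  ev_side <- character(ev_cap); ev_label <- character(ev_cap)
  ev_int <- numeric(ev_cap); ev_trial <- integer(ev_cap)
  ev_phase <- character(ev_cap); ne <- 0L
  push_ev <- function(t, kind, side, label, int, trial, phase) {
    ne <<- ne + 1L
    ev_t[ne] <<- t; ev_kind[ne] <<- kind; ev_side[ne] <<- side
    ev_label[ne] <<- label; ev_int[ne] <<- int
    ev_trial[ne] <<- trial; ev_phase[ne] <<- phase
  }
  push_ev(0, "phase_mark", "none", "DARK", 0, 0L, "habituation")

  u_left <- 0; u_right <- 0; arousal <- 1; boost <- 1
  cur_phase <- "habituation"
  shocked_side <- "none"; plus_lab <- "DARK"; plus_int <- 0
  shock_side_left <- NA  # TRUE if shocked side is left

  util <- function(stim) {
    if (stim$label == "DARK") return(0)
    params$attractiveness(stim$label, stim$intensity_pct) -
      max(0, V[[stim$label]] - s_prior[[stim$label]])
  }

  for (i in seq_len(N)) {
    si <- .sensor_index(pos, ch)
    sensor[i] <- si
    posq[i] <- if (params$quantize) (si - 0.5) * ch$pitch_cm else pos

    k <- trial_id[i]
    if (k > 0L) {
      tr <- protocol$trials[[k]]
      if (i == onset_i[k]) {
        sa <- resolve_sides(posq[i], ch, tr)
        u_left <- util(sa$left_stimulus)
        u_right <- util(sa$right_stimulus)
        shocked_side <- sa$shocked_side
        plus_lab <- tr$bee_side_light$label
        plus_int <- tr$bee_side_light$intensity_pct
        lit <- c(if (sa$left_stimulus$intensity_pct > 0) sa$left_stimulus$label,
                 if (sa$right_stimulus$intensity_pct > 0) sa$right_stimulus$label)
        arousal <- if (length(lit))
          1 + params$anticipation_gain * max(Fv[lit]) else 1
        boost <- 1
        left_stim <- sa$left_stimulus; right_stim <- sa$right_stimulus
        if (tr$phase != cur_phase) {
          push_ev(tvec[i], "phase_mark", "none", "DARK", 0, k, tr$phase)
          cur_phase <- tr$phase
        }
        off_t <- tvec[i] + tr$stimulus_duration_s
        if (left_stim$intensity_pct > 0) {
          push_ev(tvec[i], "light_on", "left", left_stim$label,
                  left_stim$intensity_pct, k, tr$phase)
          push_ev(off_t, "light_off", "left", left_stim$label,
                  left_stim$intensity_pct, k, tr$phase)
        }
        if (right_stim$intensity_pct > 0) {
          push_ev(tvec[i], "light_on", "right", right_stim$label,
                  right_stim$intensity_pct, k, tr$phase)
          push_ev(off_t, "light_off", "right", right_stim$label,
                  right_stim$intensity_pct, k, tr$phase)
        }
      }
      if (is_pulse[i] && shocked_side != "none") {
        on_shocked <- (posq[i] <= ch$midline_cm) == (shocked_side == "left")
        if (on_shocked) {
          V[[plus_lab]] <- V[[plus_lab]] + alpha * (vmax - V[[plus_lab]])
          Fv[[plus_lab]] <- Fv[[plus_lab]] +
            params$anticipation_rate * (1 - Fv[[plus_lab]])
          # re-express the shocked side's utility with the updated aversion
          if (shocked_side == "left") u_left <- util(left_stim)
          else u_right <- util(right_stim)
          boost <- params$shock_speed_factor
          push_ev(tvec[i], "shock_pulse", shocked_side, plus_lab, plus_int,
                  k, tr$phase)
        }
      }
    } else {
      u_left <- 0; u_right <- 0; arousal <- 1; boost <- 1
      shocked_side <- "none"
    }

    if (i < N) {
      ahead <- if (dir > 0L) u_right else u_left
      behind <- if (dir > 0L) u_left else u_right
      p_flip <- (1 - params$persistence) + gain * (behind - ahead)
      p_flip <- min(1, max(0, p_flip))
      if (flips[i] < p_flip) dir <- -dir
      pos <- pos + dir * speeds[i] * arousal * boost * dt
      if (pos < 0) { pos <- -pos; dir <- 1L }
      if (pos > L) { pos <- 2 * L - pos; dir <- -1L }
    }
  }

  ord <- seq_len(ne)
  events <- data.frame(
    bee_id = bee_id, t_s = ev_t[ord], kind = ev_kind[ord],
    side = ev_side[ord], label = ev_label[ord],
    intensity_pct = ev_int[ord], trial_index = ev_trial[ord],
    phase = ev_phase[ord], stringsAsFactors = FALSE)
  events <- events[order(events$t_s, method = "radix"), , drop = FALSE]
  rownames(events) <- NULL
  trace <- data.frame(
    bee_id = bee_id, t_s = tvec, position_cm = round(posq, 3),
    sensor_index = sensor, stringsAsFactors = FALSE)
  list(trace = trace, events = events)
}

#' Simulate a cohort of bees
#'
#' Runs \code{\link{simulate_bee}} for \code{n} bees with per-bee seeds (and,
#' unless a fixed \code{protocol} is supplied, per-bee protocol seeds, so
#' pseudorandomized orderings vary across the cohort as they did across real
#' bees) derived deterministically from the master \code{seed}.
#'
#' @param n Number of bees.
#' @param experiment,pair,ref,test,reinforced Protocol choices passed to
#'   \code{\link{build_protocol}} when \code{protocol} is \code{NULL}.
#' @param params An \code{\link{agent_params}} shared by the cohort.
#' @param seed Master seed.
#' @param protocol Optional fixed \code{apis_protocol} used for every bee.
#' @param chamber A \code{\link{chamber_spec}}.
#' @param bee_prefix Prefix for generated bee identifiers.
#' @return An \code{\link{apis_dataset}}: pooled traces, events, and one
#'   record per bee (bee_id, paradigm, protocol_name, excluded = NA).
#' @export
simulate_cohort <- function(n, experiment = "I", pair = "BG", ref = "B",
                            test = "G", reinforced = TRUE,
                            params = agent_params(), seed = 1L,
                            protocol = NULL, chamber = chamber_spec(),
                            bee_prefix = "bee") {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, 2L * n)
  traces <- vector("list", n); events <- vector("list", n)
  ids <- sprintf("%s%04d", bee_prefix, seq_len(n))
  names <- character(n); paradigm <- character(n)
  for (b in seq_len(n)) {
    pr <- protocol %||% build_protocol(
      experiment, pair = pair, ref = ref, test = test,
      reinforced = reinforced, seed = seeds[2L * b - 1L], chamber = chamber)
    sim <- simulate_bee(pr, params, seed = seeds[2L * b], bee_id = ids[b])
    traces[[b]] <- sim$trace; events[[b]] <- sim$events
    names[b] <- pr$name
    paradigm[b] <- if (pr$reinforced) "reinforced" else "unreinforced"
  }
  records <- data.frame(bee_id = ids, paradigm = paradigm,
                        protocol_name = names, excluded = NA,
                        stringsAsFactors = FALSE)
  apis_dataset(do.call(rbind, traces), do.call(rbind, events), records,
               chamber = chamber)
}
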