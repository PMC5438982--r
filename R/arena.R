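#' Chamber geometry
#'
#' Describes the linear walking chamber: a 1-D corridor whose two halves carry
#' independent light fields and an electrifiable grid. Bee position is sampled
#' by a row of evenly spaced infrared sensors.
#'
#' @param length_cm Chamber length in cm. The original apparatus papers give
#'   the physical dimensions; the default of 26 cm (one sensor per cm) keeps
#'   walking speeds commensurate with the 2-5 cm/s range typical of the assay.
#' @param n_sensors Number of position sensors along the chamber.
#' @param sample_rate_hz Position sampling rate in Hz.
#' @return An object of class \code{chamber_spec} with derived fields
#'   \code{midline_cm} (= length/2) and \code{pitch_cm} (= length/n_sensors).
#' @export
chamber_spec <- function(length_cm = 26, n_sensors = 26L, sample_rate_hz = 16) {
  stopifnot(is.numeric(length_cm), length_cm > 0,
            n_sensors >= 2, sample_rate_hz > 0)
  structure(list(
    length_cm      = as.numeric(length_cm),
    n_sensors      = as.integer(n_sensors),
    sample_rate_hz = as.numeric(sample_rate_hz),
    midline_cm     = as.numeric(length_cm) / 2,
    pitch_cm       = as.numeric(length_cm) / as.integer(n_sensors)
  ), class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("Linear chamber: %.1f cm, %d sensors (pitch %.2f cm), %g Hz sampling\n",
              x$length_cm, x$n_sensors, x$pitch_cm, x$sample_rate_hz))
  invisible(x)
}

# LED catalog: peak wavelength, spectral bandwidth and maximum luminous
# intensity of the three chamber LEDs (blue, green, yellow).
.led_catalog <- data.frame(
  label    = c("B", "G", "Y", "DARK"),
  peak_nm  = c(465, 525, 590, NA),
  bandwidth_nm = c(45, 45, 25, NA),
  max_mcd  = c(105, 310, 330, NA),
  stringsAsFactors = FALSE
)

#' Light stimulus
#'
#' One half-field light stimulus: an LED label (\code{"B"}, \code{"G"},
#' \code{"Y"}) at a relative intensity, or \code{"DARK"} (no light).
#'
#' @param label One of \code{"B"}, \code{"G"}, \code{"Y"}, \code{"DARK"}.
#' @param intensity_pct Relative intensity in percent of the LED maximum,
#'   in [0, 100]. Forced to 0 for \code{"DARK"}.
#' @return An object of class \code{light_source}.
#' @export
light_source <- function(label, intensity_pct = 100) {
  label <- match.arg(label, .led_catalog$label)
  if (!is.numeric(intensity_pct) || length(intensity_pct) != 1 ||
      is.na(intensity_pct) || intensity_pct < 0 || intensity_pct > 100)
    stop("intensity_pct must be a single value in [0, 100]")
  if (label == "DARK") intensity_pct <- 0
  row <- .led_catalog[.led_catalog$label == label, ]
  structure(list(
    label = label,
    peak_nm = row$peak_nm,
    bandwidth_nm = row$bandwidth_nm,
    max_luminous_intensity_mcd = row$max_mcd,
    intensity_pct = as.numeric(intensity_pct)
  ), class = "light_source")
}

#' @export
print.light_source <- function(x, ...) {
  if (x$label == "DARK") cat("DARK (no light)\n")
  else cat(sprintf("%s LED (%g nm) at %g%% intensity\n",
                   x$label, x$peak_nm, x$intensity_pct))
  invisible(x)
}

#' Shock pulse train specification
#'
#' The closed-loop punishment: brief electric pulses restricted to the
#' shocked half-field, starting a fixed delay after light onset and sharing
#' the light's offset. Defaults give 10 V / 100 ms pulses at 4 Hz from 3 s to
#' 14 s after onset, i.e. a 11 s train of 44 pulses.
#'
#' @param onset_delay_s Delay of the first pulse after light onset (s).
#' @param rate_hz Pulse rate (Hz).
#' @param pulse_width_s Pulse duration (s); informational.
#' @param end_s End of the train relative to light onset (s); shared with
#'   the light offset.
#' @param voltage_v Pulse amplitude (V); informational.
#' @return An object of class \code{shock_spec}.
#' @export
shock_spec <- function(onset_delay_s = 3, rate_hz = 4, pulse_width_s = 0.1,
                       end_s = 14, voltage_v = 10) {
  if (onset_delay_s >= end_s)
    stop("invalid shock specification: onset_delay_s must be < end_s")
  stopifnot(rate_hz > 0, pulse_width_s > 0)
  structure(list(
    onset_delay_s = as.numeric(onset_delay_s),
    rate_hz = as.numeric(rate_hz),
    pulse_width_s = as.numeric(pulse_width_s),
    end_s = as.numeric(end_s),
    voltage_v = as.numeric(voltage_v)
  ), class = "shock_spec")
}

#' Scheduled shock pulse times
#'
#' Onset-relative times of every pulse in a train: \code{delay + k/rate} for
#' \code{k = 0, ..., n-1} with \code{n = floor((end - delay) * rate)}. The
#' default specification yields 44 pulses from 3.0 s to 13.75 s.
#'
#' @param shock A \code{\link{shock_spec}}.
#' @return Numeric vector of pulse onset times (s, relative to light onset).
#' @export
shock_pulse_times <- function(shock = shock_spec()) {
  stopifnot(inherits(shock, "shock_spec"))
  n <- floor((shock$end_s - shock$onset_delay_s) * shock$rate_hz)
  shock$onset_delay_s + (seq_len(n) - 1) / shock$rate_hz
}

#' Resolve chamber sides at trial onset
#'
#' The closed-loop rule of the paradigm: the danger light (the trial's
#' bee-side stimulus) is presented on whichever chamber half contains the bee
#' at light onset, the other stimulus on the opposite half, and the shock --
#' when the trial carries one -- is restricted to the bee side. A position
#' exactly on the midline is assigned to the left half (documented
#' tie-break).
#'
#' @param position_cm Bee position at onset, in cm from the left chamber end.
#' @param chamber A \code{\link{chamber_spec}}.
#' @param trial A \code{\link{trial_spec}}.
#' @return A list of class \code{side_assignment} with fields
#'   \code{trial_index}, \code{bee_side}, \code{left_stimulus},
#'   \code{right_stimulus}, \code{shocked_side}.
#' @export
resolve_sides <- function(position_cm, chamber, trial) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(trial, "trial_spec"))
  if (!is.numeric(position_cm) || is.na(position_cm) ||
      position_cm < 0 || position_cm > chamber$length_cm)
    stop(sprintf("position %.3f cm outside chamber [0, %.3f]",
                 position_cm, chamber$length_cm))
  bee_side <- if (position_cm <= chamber$midline_cm) "left" else "right"
  left  <- if (bee_side == "left")  trial$bee_side_light else trial$opposite_side_light
  right <- if (bee_side == "right") trial$bee_side_light else trial$opposite_side_light
  shocked <- if (isTRUE(trial$shock_on_bee_side) && !is.null(trial$shock))
    bee_side else "none"
  structure(list(
    trial_index = trial$index,
    bee_side = bee_side,
    left_stimulus = left,
    right_stimulus = right,
    shocked_side = shocked
  ), class = "side_assignment")
}

# which chamber half a position falls in; midline counts as left
chamber_side <- function(position_cm, chamber) {
  ifelse(position_cm <= chamber$midline_cm, "left", "right")
}
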