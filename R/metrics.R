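#' Segment a bee's session into trial slices
#'
#' Cuts one bee's trace into per-trial windows spanning [onset - 3 s,
#' onset + 14 s). The onset is the trial's first \code{light_on} time; the
#' side layout is taken from the event log, and the focal (bee) side is the
#' chamber half containing the bee at the onset sample (midline counts as
#' left), recomputed from the trace exactly as the closed-loop controller
#' resolved it.
#'
#' @param trace One bee's trace data.frame (bee_id, t_s, position_cm,
#'   sensor_index).
#' @param events The matching event log (may contain other bees; filtered by
#'   bee_id).
#' @param chamber A \code{\link{chamber_spec}}.
#' @param pre_s,stim_s Window extents (s) before onset and of the stimulus.
#' @return A list of \code{trial_slice} objects, ordered by trial index; an
#'   empty list when the log holds no light events for the bee.
#' @export
segment_trials <- function(trace, events, chamber = chamber_spec(),
                           pre_s = 3, stim_s = 14) {
  bee <- unique(trace$bee_id)
  if (length(bee) != 1) stop("segment_trials expects a single bee's trace")
  ev <- events[events$bee_id == bee & events$kind == "light_on", , drop = FALSE]
  if (nrow(ev) == 0) return(list())
  trials <- sort(unique(ev$trial_index))
  ot <- vapply(trials, function(k) min(ev$t_s[ev$trial_index == k]), 0)
  if (any(diff(ot) < stim_s))
    stop("overlapping trials in event log for bee ", bee)
  lapply(seq_along(trials), function(j) {
    k <- trials[j]
    e <- ev[ev$trial_index == k, , drop = FALSE]
    onset <- ot[j]
    sel <- trace$t_s >= onset - pre_s & trace$t_s < onset + stim_s
    seg_t <- trace$t_s[sel]; seg_p <- trace$position_cm[sel]
    partial <- length(seg_t) < round((pre_s + stim_s) * chamber$sample_rate_hz)
    oi <- which(seg_t >= onset)[1]
    if (is.na(oi)) stop("trace does not cover onset of trial ", k,
                        " for bee ", bee)
    focal <- chamber_side(seg_p[oi], chamber)
    side_of <- function(s) {
      i <- which(e$side == s)
      if (length(i)) list(label = e$label[i[1]],
                          intensity_pct = e$intensity_pct[i[1]])
      else list(label = "DARK", intensity_pct = 0)
    }
    structure(list(
      bee_id = bee, trial_index = k, phase = e$phase[1], onset_t_s = onset,
      focal_side = focal,
      left = side_of("left"), right = side_of("right"),
      times_s = seg_t, positions_cm = seg_p,
      chamber = chamber, partial = partial
    ), class = "trial_slice")
  })
}

#' @export
print.trial_slice <- function(x, ...) {
  cat(sprintf(
    "Trial %d (%s) of %s: onset %.2f s, bee side %s; left %s@%g%%, right %s@%g%%\n",
    x$trial_index, x$phase, x$bee_id, x$onset_t_s, x$focal_side,
    x$left$label, x$left$intensity_pct, x$right$label, x$right$intensity_pct))
  invisible(x)
}

#' Preference index of one trial
#'
#' Occupancy is accumulated per 1/16 s sample over the stimulus window
#' [onset, onset + 14 s); \code{pi = (t_nonfocal - t_focal) / (t_nonfocal +
#' t_focal)}, i.e. positive when the bee avoided the stimulus presented on
#' its own side at onset (the danger light in training trials, so positive =
#' toward the safe light).
#'
#' @param slice A \code{trial_slice}.
#' @param stim_s Analyzed stimulus duration (s).
#' @return List with \code{pi}, \code{t_focal_s}, \code{t_nonfocal_s}.
#' @export
preference_index <- function(slice, stim_s = 14) {
  stopifnot(inherits(slice, "trial_slice"))
  dt <- 1 / slice$chamber$sample_rate_hz
  sel <- slice$times_s >= slice$onset_t_s &
         slice$times_s < slice$onset_t_s + stim_s
  if (!any(sel)) stop("empty stimulus window: preference index undefined")
  p <- slice$positions_cm[sel]
  on_left <- p <= slice$chamber$midline_cm
  t_left <- sum(on_left) * dt
  t_right <- sum(!on_left) * dt
  t_focal <- if (slice$focal_side == "left") t_left else t_right
  t_nonfocal <- if (slice$focal_side == "left") t_right else t_left
  list(pi = (t_nonfocal - t_focal) / (t_nonfocal + t_focal),
       t_focal_s = t_focal, t_nonfocal_s = t_nonfocal)
}

#' Actual or fictive shock count of one trial
#'
#' \code{mode = "actual"} counts the logged \code{shock_pulse} events of the
#' trial. \code{mode = "fictive"} re-derives the count the bee would have
#' received from its movement alone: at each scheduled pulse time (3--14 s
#' after onset at 4 Hz), the bee's position at the nearest preceding trace
#' sample is tested against the focal (danger-light) side.
#'
#' @param slice A \code{trial_slice}.
#' @param events Event log (needed for \code{mode = "actual"}).
#' @param mode \code{"actual"} or \code{"fictive"}.
#' @param shock The \code{\link{shock_spec}} defining the schedule.
#' @return Integer count in [0, 44] for the default schedule.
#' @export
count_shocks <- function(slice, events = NULL, mode = c("fictive", "actual"),
                         shock = shock_spec()) {
  stopifnot(inherits(slice, "trial_slice"))
  mode <- match.arg(mode)
  if (mode == "actual") {
    if (is.null(events)) stop("mode = 'actual' requires the event log")
    sum(events$bee_id == slice$bee_id &
        events$kind == "shock_pulse" &
        events$trial_index == slice$trial_index)
  } else {
    if (!slice$focal_side %in% c("left", "right"))
      stop("fictive shock count needs a resolved danger-light side")
    pt <- slice$onset_t_s + shock_pulse_times(shock)
    # position at the nearest preceding (or simultaneous) sample
    idx <- findInterval(pt + 1e-9, slice$times_s)
    if (any(idx == 0)) stop("trace does not cover the pulse schedule")
    side <- chamber_side(slice$positions_cm[idx], slice$chamber)
    sum(side == slice$focal_side)
  }
}

#' Average absolute walking speed inside a time window
#'
#' Distance covered during [t0, t1) -- the summed absolute displacement of
#' every inter-sample step starting inside the window -- divided by the
#' window duration.
#'
#' @param times_s,positions_cm The trace (or a segment of it).
#' @param t0,t1 Window bounds in seconds, t0 < t1.
#' @return Speed in cm/s.
#' @export
window_speed <- function(times_s, positions_cm, t0, t1) {
  stopifnot(t0 < t1, length(times_s) == length(positions_cm))
  i <- which(times_s >= t0 & times_s < t1)
  if (length(i) < 2) stop(sprintf("trace does not cover window [%g, %g)", t0, t1))
  step <- stats::median(diff(times_s[i]))
  if (min(times_s) > t0 + 1e-9 || max(times_s) < t1 - step - 1e-9)
    stop(sprintf("trace does not cover window [%g, %g)", t0, t1))
  if (max(i) == length(times_s))
    i <- i[-length(i)]  # final step leaves the trace; drop it
  sum(abs(positions_cm[i + 1L] - positions_cm[i])) / (t1 - t0)
}

#' Pre- and post-onset speeds of one trial
#'
#' Absolute speed in the 3 s windows just before ([onset - 3, onset)) and
#' just after ([onset, onset + 3)) light onset.
#'
#' @param slice A \code{trial_slice}.
#' @param window_s Window length in seconds.
#' @return List with \code{speed_pre_cm_s} and \code{speed_post_cm_s}.
#' @export
pre_post_speed <- function(slice, window_s = 3) {
  stopifnot(inherits(slice, "trial_slice"))
  list(speed_pre_cm_s = window_speed(slice$times_s, slice$positions_cm,
                                     slice$onset_t_s - window_s,
                                     slice$onset_t_s),
       speed_post_cm_s = window_speed(slice$times_s, slice$positions_cm,
                                      slice$onset_t_s,
                                      slice$onset_t_s + window_s))
}

#' Per-trial metrics table for one bee
#'
#' Runs the full trial pipeline -- segmentation, preference index, shock
#' count (actual for reinforced training trials, fictive otherwise),
#' pre/post/full-trial speeds -- and returns one row per trial.
#'
#' @param trace,events One bee's trace and the event log.
#' @param paradigm \code{"reinforced"} or \code{"unreinforced"}; decides
#'   whether training-trial shock counts are actual or fictive.
#' @param chamber A \code{\link{chamber_spec}}.
#' @param shock The \code{\link{shock_spec}} schedule.
#' @return data.frame with columns bee_id, trial_index, phase, onset_t_s,
#'   focal_side, focal_label, focal_intensity_pct, opposite_label,
#'   opposite_intensity_pct, t_focal_s, t_nonfocal_s, pi, shocks,
#'   shock_mode, speed_pre_cm_s, speed_post_cm_s, speed_trial_cm_s.
#' @export
trial_metrics <- function(trace, events, paradigm = "unreinforced",
                          chamber = chamber_spec(), shock = shock_spec()) {
  slices <- segment_trials(trace, events, chamber)
  if (!length(slices)) return(NULL)
  rows <- lapply(slices, function(s) {
    pi <- preference_index(s)
    sp <- pre_post_speed(s)
    mode <- if (paradigm == "reinforced" && s$phase == "training")
      "actual" else "fictive"
    shocks <- count_shocks(s, events, mode, shock)
    focal <- if (s$focal_side == "left") s$left else s$right
    opp <- if (s$focal_side == "left") s$right else s$left
    data.frame(
      bee_id = s$bee_id, trial_index = s$trial_index, phase = s$phase,
      onset_t_s = s$onset_t_s, focal_side = s$focal_side,
      focal_label = focal$label, focal_intensity_pct = focal$intensity_pct,
      opposite_label = opp$label, opposite_intensity_pct = opp$intensity_pct,
      t_focal_s = pi$t_focal_s, t_nonfocal_s = pi$t_nonfocal_s, pi = pi$pi,
      shocks = shocks, shock_mode = mode,
      speed_pre_cm_s = sp$speed_pre_cm_s,
      speed_post_cm_s = sp$speed_post_cm_s,
      speed_trial_cm_s = window_speed(s$times_s, s$positions_cm,
                                      s$onset_t_s, s$onset_t_s + 14),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Speed change from first training to first test trial
#'
#' \code{delta = speed(first test trial) - speed(first training trial)},
#' computed separately for the pre-onset and post-onset 3 s windows, plus
#' each as a percentage of the first training trial's value.
#'
#' @param metrics A \code{\link{trial_metrics}} table for one bee.
#' @return List with \code{delta_pre}, \code{delta_post}, \code{pct_pre},
#'   \code{pct_post} (cm/s and percent).
#' @export
delta_speed <- function(metrics) {
  tr <- metrics[metrics$phase == "training", , drop = FALSE]
  te <- metrics[metrics$phase == "test", , drop = FALSE]
  if (!nrow(tr) || !nrow(te))
    stop("delta_speed needs at least one training and one test trial")
  tr1 <- tr[which.min(tr$trial_index), ]
  te1 <- te[which.min(te$trial_index), ]
  d_pre <- te1$speed_pre_cm_s - tr1$speed_pre_cm_s
  d_post <- te1$speed_post_cm_s - tr1$speed_post_cm_s
  list(delta_pre = d_pre, delta_post = d_post,
       pct_pre = 100 * d_pre / tr1$speed_pre_cm_s,
       pct_post = 100 * d_post / tr1$speed_post_cm_s)
}

#' Flag exhausted bees
#'
#' A bee is excluded when its average full-trial speed over the test trials
#' is strictly below \code{threshold_cm_s} (a bee at exactly the threshold
#' is retained). Excluded bees stay in the data; only the flag is set.
#'
#' @param bee_summary A \code{\link{summarize_bees}} table (needs columns
#'   \code{mean_test_speed_cm_s}).
#' @param threshold_cm_s Exclusion threshold in cm/s.
#' @return The table with its \code{excluded} column set.
#' @export
apply_exclusion <- function(bee_summary, threshold_cm_s = 2) {
  if (any(is.na(bee_summary$mean_test_speed_cm_s)))
    stop("bees without test trials cannot be screened for exclusion")
  bee_summary$excluded <- bee_summary$mean_test_speed_cm_s < threshold_cm_s
  bee_summary
}

#' Per-bee summary table
#'
#' One row per bee: speed change (\code{\link{delta_speed}}), mean full-trial
#' test speed, and the exclusion flag at the given threshold. Experiment III
#' style protocols (no training/test phases) get NA speed changes and are
#' screened on their preference trials instead.
#'
#' @param metrics Pooled \code{\link{trial_metrics}} rows for all bees.
#' @param records The per-bee records table of the dataset.
#' @param threshold_cm_s Exclusion threshold (cm/s).
#' @return data.frame, one row per bee.
#' @export
summarize_bees <- function(metrics, records, threshold_cm_s = 2) {
  rows <- lapply(records$bee_id, function(b) {
    m <- metrics[metrics$bee_id == b, , drop = FALSE]
    test <- m[m$phase == "test", , drop = FALSE]
    if (!nrow(test)) test <- m[m$phase == "preference", , drop = FALSE]
    ds <- if (any(m$phase == "training") && any(m$phase == "test"))
      delta_speed(m)
    else list(delta_pre = NA_real_, delta_post = NA_real_,
              pct_pre = NA_real_, pct_post = NA_real_)
    data.frame(
      bee_id = b,
      paradigm = records$paradigm[records$bee_id == b],
      protocol_name = records$protocol_name[records$bee_id == b],
      n_trials = nrow(m),
      delta_speed_pre = ds$delta_pre, delta_speed_post = ds$delta_post,
      delta_speed_pre_pct = ds$pct_pre, delta_speed_post_pct = ds$pct_post,
      mean_test_speed_cm_s = if (nrow(test))
        mean(test$speed_trial_cm_s) else NA_real_,
      excluded = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  apply_exclusion(out, threshold_cm_s)
}

#' Cohort summary: per-trial group means
#'
#' Mean and standard error (sd/sqrt(n)) of preference index, shock count and
#' pre/post speeds per (paradigm, protocol, phase, trial), over non-excluded
#' bees. Single-bee cells get an NA SEM; empty groups are absent rather than
#' zero.
#'
#' @param metrics Pooled \code{\link{trial_metrics}} rows.
#' @param bee_summary A \code{\link{summarize_bees}} table with exclusion
#'   flags set.
#' @return data.frame, one row per (paradigm, protocol_name, phase,
#'   trial_index) with n, mean and sem columns for each metric.
#' @export
summarize_cohort <- function(metrics, bee_summary) {
  keep <- bee_summary$bee_id[!bee_summary$excluded]
  if (!length(keep)) stop("no analyzable bees: every bee is excluded")
  m <- merge(metrics[metrics$bee_id %in% keep, , drop = FALSE],
             bee_summary[, c("bee_id", "paradigm", "protocol_name")],
             by = "bee_id")
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  agg <- function(col) {
    a <- stats::aggregate(
      m[[col]],
      by = m[c("paradigm", "protocol_name", "phase", "trial_index")],
      FUN = function(v) c(n = length(v), mean = mean(v), sem = sem(v)))
    cbind(a[, 1:4], stats::setNames(as.data.frame(a$x),
                                    c("n", paste0("mean_", col), paste0("sem_", col))))
  }
  out <- agg("pi")
  for (col in c("shocks", "speed_pre_cm_s", "speed_post_cm_s")) {
    a <- agg(col)
    out <- merge(out, a[, -match("n", names(a))],
                 by = c("paradigm", "protocol_name", "phase", "trial_index"))
  }
  out[order(out$paradigm, out$protocol_name, out$trial_index), , drop = FALSE]
}

#' Metrics for every bee of a dataset
#'
#' Convenience wrapper running \code{\link{trial_metrics}} across a cohort.
#'
#' @param dataset An \code{\link{apis_dataset}}.
#' @param shock The \code{\link{shock_spec}} schedule.
#' @return Pooled per-trial metrics data.frame.
#' @export
dataset_metrics <- function(dataset, shock = shock_spec()) {
  stopifnot(inherits(dataset, "apis_dataset"))
  rows <- lapply(seq_len(nrow(dataset$records)), function(j) {
    b <- dataset$records$bee_id[j]
    trial_metrics(dataset$traces[dataset$traces$bee_id == b, , drop = FALSE],
                  dataset$events[dataset$events$bee_id == b, , drop = FALSE],
                  paradigm = dataset$records$paradigm[j],
                  chamber = dataset$chamber, shock = shock)
  })
  do.call(rbind, rows)
}
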