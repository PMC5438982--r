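.apisim_schema <- "apisim-dataset/1"

#' Cohort dataset container
#'
#' Bundles the three interchange tables of a cohort run: the 16 Hz position
#' traces, the timestamped stimulus/shock event log, and per-bee metadata.
#'
#' @param traces data.frame with columns \code{bee_id}, \code{t_s},
#'   \code{position_cm}, \code{sensor_index}.
#' @param events data.frame with columns \code{bee_id}, \code{t_s},
#'   \code{kind} (\code{light_on}, \code{light_off}, \code{shock_pulse},
#'   \code{phase_mark}), \code{side} (\code{left}, \code{right}, \code{both},
#'   \code{none}), \code{label}, \code{intensity_pct}, \code{trial_index},
#'   \code{phase}.
#' @param records data.frame with columns \code{bee_id}, \code{paradigm}
#'   (\code{reinforced}/\code{unreinforced}), \code{protocol_name},
#'   \code{excluded} (logical or NA while pending).
#' @param chamber A \code{\link{chamber_spec}}.
#' @param validate Whether to run \code{\link{validate_dataset}}.
#' @return An object of class \code{apis_dataset}.
#' @export
apis_dataset <- function(traces, events, records, chamber = chamber_spec(),
                         validate = TRUE) {
  x <- structure(list(traces = traces, events = events, records = records,
                      chamber = chamber, schema = .apisim_schema),
                 class = "apis_dataset")
  if (validate) validate_dataset(x)
  x
}

#' @export
print.apis_dataset <- function(x, ...) {
  cat(sprintf("Cohort dataset: %d bees, %d trace samples, %d events\n",
              nrow(x$records), nrow(x$traces), nrow(x$events)))
  if (nrow(x$records)) {
    tab <- table(x$records$paradigm, x$records$protocol_name)
    print(tab)
  }
  invisible(x)
}

.required_trace_cols <- c("bee_id", "t_s", "position_cm", "sensor_index")
.required_event_cols <- c("bee_id", "t_s", "kind", "side", "label",
                          "intensity_pct", "trial_index", "phase")
.required_record_cols <- c("bee_id", "paradigm", "protocol_name", "excluded")

#' Validate a cohort dataset
#'
#' Re-checks every structural invariant of the interchange format: column
#' schemas; per-bee strictly increasing trace times; positions within the
#' chamber; known event kinds and sides; exactly one light_on and one
#' light_off per illuminated side per trial; shock pulses only inside the
#' scheduled [onset + 3 s, onset + 14 s) window; and paradigm consistency
#' (unreinforced bees carry no shock events). Violations are reported with
#' the offending bee and row.
#'
#' @param x An \code{apis_dataset}.
#' @param shock The \code{\link{shock_spec}} defining the legal pulse window.
#' @return \code{x}, invisibly; stops with a descriptive error on violation.
#' @export
validate_dataset <- function(x, shock = shock_spec()) {
  stopifnot(inherits(x, "apis_dataset"))
  tr <- x$traces; ev <- x$events; rec <- x$records
  if (!all(.required_trace_cols %in% names(tr)))
    stop("traces missing columns: ",
         paste(setdiff(.required_trace_cols, names(tr)), collapse = ", "))
  if (!all(.required_event_cols %in% names(ev)))
    stop("events missing columns: ",
         paste(setdiff(.required_event_cols, names(ev)), collapse = ", "))
  if (!all(.required_record_cols %in% names(rec)))
    stop("records missing columns: ",
         paste(setdiff(.required_record_cols, names(rec)), collapse = ", "))

  bad <- which(tr$position_cm < 0 | tr$position_cm > x$chamber$length_cm)
  if (length(bad))
    stop(sprintf("trace row %d (bee %s): position %.3f cm outside chamber [0, %g]",
                 bad[1], tr$bee_id[bad[1]], tr$position_cm[bad[1]],
                 x$chamber$length_cm))
  for (b in unique(tr$bee_id)) {
    tt <- tr$t_s[tr$bee_id == b]
    nm <- which(diff(tt) <= 0)
    if (length(nm))
      stop(sprintf("trace times not strictly increasing for bee %s (sample %d)",
                   b, nm[1] + 1L))
  }

  ok_kind <- ev$kind %in% c("light_on", "light_off", "shock_pulse", "phase_mark")
  if (!all(ok_kind))
    stop(sprintf("event row %d: unknown kind '%s'",
                 which(!ok_kind)[1], ev$kind[which(!ok_kind)[1]]))
  ok_side <- ev$side %in% c("left", "right", "both", "none")
  if (!all(ok_side))
    stop(sprintf("event row %d: unknown side '%s'",
                 which(!ok_side)[1], ev$side[which(!ok_side)[1]]))

  # per (bee, trial): paired light events; shock pulses inside the window
  lev <- ev[ev$kind %in% c("light_on", "light_off"), , drop = FALSE]
  if (nrow(lev)) {
    key <- paste(lev$bee_id, lev$trial_index, lev$side, lev$kind)
    dup <- duplicated(key)
    if (any(dup))
      stop(sprintf("event row %d: duplicate %s for bee %s trial %d side %s",
                   which(ev$kind %in% c("light_on", "light_off"))[dup][1],
                   lev$kind[dup][1], lev$bee_id[dup][1],
                   lev$trial_index[dup][1], lev$side[dup][1]))
    on_key <- paste(lev$bee_id, lev$trial_index, lev$side)[lev$kind == "light_on"]
    off_key <- paste(lev$bee_id, lev$trial_index, lev$side)[lev$kind == "light_off"]
    if (!setequal(on_key, off_key))
      stop("unmatched light_on/light_off events: ",
           paste(c(setdiff(on_key, off_key), setdiff(off_key, on_key))[1],
                 collapse = ", "))
  }
  sp <- which(ev$kind == "shock_pulse")
  if (length(sp)) {
    on <- ev[ev$kind == "light_on", , drop = FALSE]
    onset <- tapply(on$t_s, paste(on$bee_id, on$trial_index), min)
    key <- paste(ev$bee_id[sp], ev$trial_index[sp])
    o <- onset[key]
    relt <- ev$t_s[sp] - as.numeric(o)
    bad <- which(is.na(o) | relt < shock$onset_delay_s | relt >= shock$end_s)
    if (length(bad))
      stop(sprintf(
        "event row %d (bee %s, trial %d): shock_pulse at %.3f s after onset, outside [%g, %g) s",
        sp[bad[1]], ev$bee_id[sp[bad[1]]], ev$trial_index[sp[bad[1]]],
        relt[bad[1]], shock$onset_delay_s, shock$end_s))
    shocked_bees <- unique(ev$bee_id[sp])
    unr <- rec$bee_id[rec$paradigm == "unreinforced"]
    viol <- intersect(shocked_bees, unr)
    if (length(viol))
      stop("unreinforced bee(s) with logged shock events: ",
           paste(viol, collapse = ", "))
  }
  invisible(x)
}

#' Write / read a cohort dataset
#'
#' The on-disk interchange format: \code{traces.csv} (positions at 3-decimal
#' precision), \code{events.csv}, and \code{cohort.json} (records, chamber,
#' schema version). \code{read_dataset} re-validates every invariant on load.
#'
#' @param x An \code{apis_dataset}.
#' @param path Directory to write into / read from (created if needed).
#' @return \code{write_dataset}: \code{path}, invisibly.
#'   \code{read_dataset}: the reconstructed \code{apis_dataset}.
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "apis_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  tr <- x$traces
  tr$position_cm <- round(tr$position_cm, 3)
  utils::write.csv(tr, file.path(path, "traces.csv"), row.names = FALSE)
  utils::write.csv(x$events, file.path(path, "events.csv"), row.names = FALSE)
  meta <- list(schema = x$schema,
               chamber = unclass(x$chamber)[c("length_cm", "n_sensors",
                                              "sample_rate_hz")],
               records = x$records)
  jsonlite::write_json(meta, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  fs <- file.path(path, c("traces.csv", "events.csv", "cohort.json"))
  missing <- fs[!file.exists(fs)]
  if (length(missing))
    stop("dataset files not found: ", paste(missing, collapse = ", "))
  traces <- utils::read.csv(fs[1], stringsAsFactors = FALSE,
                            colClasses = c(bee_id = "character"))
  events <- utils::read.csv(fs[2], stringsAsFactors = FALSE,
                            colClasses = c(bee_id = "character"))
  meta <- jsonlite::read_json(fs[3], simplifyVector = TRUE)
  if (!identical(meta$schema, .apisim_schema))
    stop("unrecognized dataset schema: ", meta$schema)
  records <- as.data.frame(meta$records, stringsAsFactors = FALSE)
  if (nrow(records) == 0)
    records <- data.frame(bee_id = character(), paradigm = character(),
                          protocol_name = character(), excluded = logical(),
                          stringsAsFactors = FALSE)
  records$excluded <- as.logical(records$excluded)
  chamber <- do.call(chamber_spec, meta$chamber)
  apis_dataset(traces, events, records, chamber = chamber, validate = TRUE)
}
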