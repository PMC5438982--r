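#' Simulate a cohort and write it to disk
#'
#' End-to-end "simulate" entry point: builds the requested protocol family,
#' runs \code{\link{simulate_cohort}}, writes the dataset files
#' (\code{traces.csv}, \code{events.csv}, \code{cohort.json}) plus a
#' \code{provenance.json} recording the seed, configuration and package
#' version.
#'
#' @param outdir Output directory.
#' @param experiment,pair,ref,test,reinforced Protocol choices (see
#'   \code{\link{build_protocol}}).
#' @param n Number of bees.
#' @param seed Master seed.
#' @param params An \code{\link{agent_params}}.
#' @param chamber A \code{\link{chamber_spec}}.
#' @param quiet Suppress progress messages.
#' @return The simulated \code{\link{apis_dataset}}, invisibly.
#' @export
run_simulate <- function(outdir, experiment = "I", pair = "BG", ref = "B",
                         test = "G", n = 30, reinforced = TRUE, seed = 1L,
                         params = agent_params(), chamber = chamber_spec(),
                         quiet = FALSE) {
  ds <- simulate_cohort(n, experiment = experiment, pair = pair, ref = ref,
                        test = test, reinforced = reinforced, params = params,
                        seed = seed, chamber = chamber)
  write_dataset(ds, outdir)
  prov <- list(
    tool = "apisim", version = as.character(utils::packageVersion("apisim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(experiment = experiment, pair = pair, ref = ref,
                  test = test, n = n, reinforced = reinforced,
                  chamber = unclass(chamber)[c("length_cm", "n_sensors",
                                               "sample_rate_hz")]))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet)
    message(sprintf("simulated %d bees (%s) into %s", n,
                    if (reinforced) "reinforced" else "unreinforced", outdir))
  invisible(ds)
}

#' Analyze a cohort dataset
#'
#' End-to-end "analyze" entry point: validates and loads a dataset (or takes
#' one in memory), computes per-trial metrics, per-bee summaries with
#' exclusion flags, and per-group trial summaries, writes
#' \code{trial_metrics.csv}, \code{bee_summary.csv} and
#' \code{group_stats.csv}, and reports how many bees the speed criterion
#' excluded.
#'
#' @param input An \code{\link{apis_dataset}} or a directory written by
#'   \code{\link{run_simulate}}/\code{\link{write_dataset}}.
#' @param outdir Output directory (defaults to the input directory when the
#'   input is a path).
#' @param threshold_cm_s Exclusion threshold (cm/s) on mean test-trial speed.
#' @param quiet Suppress messages.
#' @return List with \code{metrics}, \code{bees}, \code{groups}, invisibly.
#' @export
run_analyze <- function(input, outdir = NULL, threshold_cm_s = 2,
                        quiet = FALSE) {
  ds <- if (inherits(input, "apis_dataset")) input else read_dataset(input)
  if (is.null(outdir))
    outdir <- if (is.character(input)) input else stop("outdir required")
  if (nrow(ds$records) == 0) stop("empty dataset: no bees to analyze")
  metrics <- dataset_metrics(ds)
  bees <- summarize_bees(metrics, ds$records, threshold_cm_s)
  n_exc <- sum(bees$excluded)
  if (!quiet)
    message(sprintf("excluded %d of %d bees (%d%%) below %g cm/s",
                    n_exc, nrow(bees), round(100 * n_exc / nrow(bees)),
                    threshold_cm_s))
  groups <- summarize_cohort(metrics, bees)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics, file.path(outdir, "trial_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bees, file.path(outdir, "bee_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(groups, file.path(outdir, "group_stats.csv"),
                   row.names = FALSE)
  invisible(list(metrics = metrics, bees = bees, groups = groups))
}

#' Fit intensity-preference curves from analyzed metrics
#'
#' "fit-preference" entry point: takes a trial-metrics table (or the
#' directory holding \code{trial_metrics.csv}), fits the saturating
#' preference curve for one light pair and writes/extends
#' \code{mm_fits.csv}.
#'
#' @param input Metrics data.frame or analysis directory.
#' @param ref,test LED labels of the pair.
#' @param outdir Directory for \code{mm_fits.csv} (optional).
#' @param sign Orientation passed to \code{\link{preference_table}}.
#' @return The \code{mm_fit}, invisibly.
#' @export
run_fit_preference <- function(input, ref = "B", test = "G", outdir = NULL,
                               sign = 1) {
  metrics <- if (is.data.frame(input)) input
  else utils::read.csv(file.path(input, "trial_metrics.csv"),
                       stringsAsFactors = FALSE)
  fit <- fit_preference_curve(metrics, ref, test, sign)
  if (!is.null(outdir) || is.character(input)) {
    outdir <- outdir %||% input
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cf <- coef(fit)
    row <- data.frame(pair = fit$pair, a = cf[["a"]], b = cf[["b"]],
                      c = cf[["c"]], x0 = fit$x0, sse = fit$sse,
                      n = fit$n_points, converged = fit$converged)
    path <- file.path(outdir, "mm_fits.csv")
    if (file.exists(path)) {
      old <- utils::read.csv(path, stringsAsFactors = FALSE)
      row <- rbind(old[old$pair != row$pair, , drop = FALSE], row)
    }
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(fit)
}

#' Summary figure for an analyzed cohort
#'
#' "report" entry point: draws the standard four-panel learning-curve figure
#' (per-trial preference index, shock counts, post-onset speed by group, and
#' per-bee post-onset speed change) from the analysis outputs, to a PDF.
#'
#' @param input The list returned by \code{\link{run_analyze}} or the
#'   directory holding its CSV files.
#' @param file Output PDF path.
#' @return \code{file}, invisibly.
#' @export
run_report <- function(input, file = "report.pdf") {
  if (is.character(input)) {
    groups <- utils::read.csv(file.path(input, "group_stats.csv"),
                              stringsAsFactors = FALSE)
    bees <- utils::read.csv(file.path(input, "bee_summary.csv"),
                            stringsAsFactors = FALSE)
  } else {
    groups <- input$groups; bees <- input$bees
  }
  if (!nrow(groups)) stop("no analyzable bees to report on")
  grDevices::pdf(file, width = 9, height = 7)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(old); grDevices::dev.off() })
  panel <- function(col, ylab, main) {
    paradigms <- unique(groups$paradigm)
    cols <- stats::setNames(c("firebrick", "steelblue")[seq_along(paradigms)],
                            paradigms)
    graphics::plot(range(groups$trial_index),
                   range(groups[[paste0("mean_", col)]], na.rm = TRUE),
                   type = "n", xlab = "trial", ylab = ylab, main = main)
    for (p in paradigms) {
      g <- groups[groups$paradigm == p, ]
      g <- g[order(g$trial_index), ]
      graphics::lines(g$trial_index, g[[paste0("mean_", col)]],
                      type = "b", pch = 19, col = cols[[p]])
      s <- g[[paste0("sem_", col)]]
      ok <- !is.na(s) & s > 1e-9  # zero-length error bars draw nothing
      graphics::arrows(g$trial_index[ok],
                       g[[paste0("mean_", col)]][ok] - s[ok],
                       g$trial_index[ok],
                       g[[paste0("mean_", col)]][ok] + s[ok],
                       angle = 90, code = 3, length = 0.02, col = cols[[p]])
    }
    graphics::legend("topleft", legend = paradigms, col = cols, lty = 1,
                     bty = "n", cex = 0.8)
  }
  panel("pi", "preference index", "Preference over trials")
  panel("shocks", "shocks (actual/fictive)", "Shock exposure")
  panel("speed_post_cm_s", "post-onset speed (cm/s)", "Speed response")
  keep <- bees[!bees$excluded & !is.na(bees$delta_speed_post), ]
  if (nrow(keep)) {
    graphics::boxplot(delta_speed_post ~ paradigm, data = keep,
                      ylab = expression(Delta * "speed post (cm/s)"),
                      main = "Speed change, first training to first test")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(file)
}
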