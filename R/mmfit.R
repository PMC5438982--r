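#' Fit a saturating intensity-preference curve
#'
#' Fits \code{y = a + b * x / (c + x)} -- a Michaelis-Menten curve -- to
#' preference-index values observed over relative test-light intensities,
#' by least squares (Levenberg-Marquardt, with the half-saturation constant
#' constrained positive). \code{a} is the baseline preference at zero test
#' intensity, \code{a + b} the asymptotic preference, and \code{c} the
#' intensity (percent) of half-saturation. The zero-preference intensity
#' \code{x0} -- the test intensity at which the fitted curve crosses y = 0 --
#' is solved in closed form (\code{\link{zero_preference}}).
#'
#' Starting values are \code{a = mean y at x = 0}, \code{b = y(max x) -
#' y(0)}, \code{c = midrange of x}. A constant response returns a degenerate
#' fit with \code{b = 0} and no crossing; non-convergence is flagged on the
#' returned object, never silent.
#'
#' @param x Intensities in percent (at least 4 distinct values including 0),
#'   or a formula \code{y ~ x}.
#' @param y Preference-index values matching \code{x}.
#' @param data For the formula method, a data.frame holding the variables.
#' @param x_range Interval within which a zero crossing is reported.
#' @param ... Unused.
#' @return An object of class \code{mm_fit} with components
#'   \code{coefficients} (a, b, c), \code{x0}, \code{converged},
#'   \code{residuals}, \code{fitted.values}, \code{sse}, \code{n_points},
#'   \code{data}.
#' @examples
#' x <- seq(0, 100, 10)
#' y <- -0.5 + 1.0 * x / (30 + x)
#' fit <- fit_mm(x, y)
#' coef(fit)
#' zero_preference(fit)  # 30
#' @export
fit_mm <- function(x, ...) UseMethod("fit_mm")

#' @rdname fit_mm
#' @export
fit_mm.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  fit <- fit_mm.default(mf[[2]], mf[[1]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname fit_mm
#' @export
fit_mm.default <- function(x, y, x_range = c(0, 100), ...) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4 || !any(x == 0))
    stop("fit_mm needs at least 4 distinct intensities including x = 0")

  a0 <- mean(y[x == 0])
  b0 <- mean(y[x == max(x)]) - a0
  c0 <- (min(x) + max(x)) / 2
  if (c0 <= 0) c0 <- max(x) / 2

  degenerate <- stats::sd(y) < 1e-12
  if (degenerate) {
    cf <- c(a = mean(y), b = 0, c = c0)
    fitted <- rep(mean(y), length(y)); converged <- TRUE
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + b * x / (c + x),
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(a = -Inf, b = -Inf, c = 1e-9),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      cf <- c(a = a0, b = b0, c = c0)
      fitted <- cf[1] + cf[2] * x / (cf[3] + x)
      converged <- FALSE
    } else {
      cf <- stats::coef(fit)
      fitted <- as.numeric(stats::fitted(fit))
      converged <- fit$convInfo$isConv %||% TRUE
    }
  }
  res <- y - fitted
  obj <- structure(list(
    coefficients = cf, converged = converged,
    residuals = res, fitted.values = fitted,
    sse = sum(res^2), n_points = length(y),
    data = data.frame(x = x, y = y), x_range = x_range,
    call = match.call()
  ), class = "mm_fit")
  obj$x0 <- zero_preference(obj)
  obj
}

#' Zero-preference intensity of a fitted curve
#'
#' Solves \code{a + b * x / (c + x) = 0} for x: in closed form
#' \code{x0 = -a * c / (a + b)}. A crossing is reported only when the curve
#' actually passes through zero inside \code{x_range}, i.e. when \code{a}
#' and the asymptote \code{a + b} have opposite signs and the root falls in
#' the interval; \code{a = 0} gives \code{x0 = 0} (zero preference at zero
#' intensity). Otherwise \code{NA}: one light is preferred over every tested
#' intensity of the other.
#'
#' @param fit An \code{mm_fit}, or a named vector/list with a, b, c.
#' @param x_range Interval of admissible crossings (percent).
#' @return The zero-preference intensity, or \code{NA} if the curve does not
#'   cross zero in range.
#' @export
zero_preference <- function(fit, x_range = NULL) {
  if (inherits(fit, "mm_fit")) {
    cf <- fit$coefficients
    x_range <- x_range %||% fit$x_range
  } else {
    cf <- unlist(fit)[c("a", "b", "c")]
    x_range <- x_range %||% c(0, 100)
  }
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
  if (a == 0) return(0)
  if (a + b == 0) return(NA_real_)          # asymptote never crosses zero
  if (sign(a) == sign(a + b)) return(NA_real_)
  x0 <- -a * cc / (a + b)
  if (x0 > x_range[1] && x0 <= x_range[2]) x0 else NA_real_
}

#' @export
coef.mm_fit <- function(object, ...) object$coefficients

#' @export
fitted.mm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  cf[["a"]] + cf[["b"]] * x / (cf[["c"]] + x)
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Saturating intensity-preference fit: y = a + b*x/(c + x)\n")
  cat(sprintf("  a = %.*g, b = %.*g, c = %.*g%%\n",
              digits, cf[["a"]], digits, cf[["b"]], digits, cf[["c"]]))
  if (is.na(x$x0))
    cat("  no zero-preference crossing in range (one light preferred throughout)\n")
  else cat(sprintf("  zero-preference intensity x0 = %.*g%%\n", digits, x$x0))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat(sprintf("  n = %d points, SSE = %.4g, RMSE = %.4g\n",
              f$n_points, f$sse, sqrt(f$sse / f$n_points)))
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...,
                        xlab = "test-light intensity (%)",
                        ylab = "preference index") {
  d <- x$data
  graphics::plot(d$x, d$y, xlab = xlab, ylab = ylab,
                 ylim = range(c(d$y, 0)), pch = 19, ...)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "grey40")
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$x0)) graphics::abline(v = x$x0, lty = 2)
  invisible(x)
}

#' Oriented preference table for an intensity series
#'
#' Builds the per-intensity mean preference table an intensity-series
#' protocol is fitted on. Trial-level preference indices (positive = away
#' from the bee-side stimulus) are re-oriented so that positive means
#' "toward the test light": trials where the test light itself sat on the
#' bee side have their sign flipped, then the two reciprocal presentations
#' and both series directions are pooled per intensity. The orientation can
#' be reversed with \code{sign}.
#'
#' @param metrics Pooled \code{\link{trial_metrics}} rows from an intensity
#'   series (preference phase).
#' @param ref,test Reference and test LED labels.
#' @param sign +1 (default, positive toward the test light) or -1.
#' @return data.frame with columns \code{intensity_pct}, \code{n},
#'   \code{mean_pi}, \code{sem_pi}.
#' @export
preference_table <- function(metrics, ref, test, sign = 1) {
  m <- metrics[metrics$phase == "preference", , drop = FALSE]
  # a 0% test light is unlit, so its side shows up as DARK in the log
  m <- m[(m$focal_label == ref & m$opposite_label %in% c(test, "DARK")) |
         (m$focal_label %in% c(test, "DARK") & m$opposite_label == ref),
         , drop = FALSE]
  if (!nrow(m)) stop("no preference trials for pair ", ref, "/", test)
  test_on_bee_side <- m$opposite_label == ref
  oriented <- ifelse(test_on_bee_side, -m$pi, m$pi) * sign
  intensity <- ifelse(test_on_bee_side, m$focal_intensity_pct,
                      m$opposite_intensity_pct)
  agg <- stats::aggregate(oriented, by = list(intensity_pct = intensity),
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v))))
  out <- cbind(agg["intensity_pct"],
               stats::setNames(as.data.frame(agg$x), c("n", "mean_pi", "sem_pi")))
  out[order(out$intensity_pct), , drop = FALSE]
}

#' Fit preference curves for an intensity-series cohort
#'
#' Convenience wrapper: \code{\link{preference_table}} then
#' \code{\link{fit_mm}} on the per-intensity means.
#'
#' @param metrics Pooled trial metrics of the cohort.
#' @param ref,test LED labels of the pair.
#' @param sign Orientation passed to \code{\link{preference_table}}.
#' @return An \code{mm_fit}; the preference table is attached as
#'   \code{$table}.
#' @export
fit_preference_curve <- function(metrics, ref, test, sign = 1) {
  tab <- preference_table(metrics, ref, test, sign)
  fit <- fit_mm(tab$intensity_pct, tab$mean_pi)
  fit$table <- tab
  fit$pair <- paste0(ref, test)
  fit
}
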