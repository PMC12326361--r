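#' Estimate log K_OW from a measurement series
#'
#' `kow_fit()` is the central fitting function of the package. It reduces a
#' series of biphasic partition measurements to the octanol-water partition
#' coefficient at zero solute concentration, by one of two routes:
#'
#' \describe{
#'   \item{`"ph_extrapolation"` (Method 1)}{For ionizable solutes. The
#'     measured log D values are regressed linearly on the aqueous-phase pH
#'     and extrapolated to pH 7 - the pH the aqueous phase attains at zero
#'     solute concentration - giving log D_OW. This is converted to
#'     log K_OW with the ionization correction evaluated at pH 7
#'     (see [logp_from_logd]).}
#'   \item{`"conc_extrapolation"` (Method 2)}{Each measured log D is first
#'     converted to log P with that measurement's own pH, then log P is
#'     regressed linearly on the overall solute concentration and the
#'     intercept at c = 0 is log K_OW. For neutral solutes log D = log P
#'     and this route (without any conversion) is the only one available.}
#' }
#'
#' Fits are ordinary least squares via [stats::lm]; when every measurement
#' carries replicate standard deviations for both phases, inverse-variance
#' weights propagated to the log scale are used instead. Reported standard
#' errors reflect fit uncertainty only (pKa uncertainty is not propagated).
#' An `extrapolation_span_warning` is set when the distance from the data to
#' the extrapolation target exceeds the span of the data itself.
#'
#' @param series A [measurement_series].
#' @param method `"auto"` (pH extrapolation for ionizable solutes,
#'   concentration extrapolation for neutral ones), `"ph_extrapolation"`,
#'   or `"conc_extrapolation"`.
#' @return An object of class `kow_fit` with components `method`,
#'   `log_value` (the log K_OW estimate), `std_error`,
#'   `intermediate_logDow` (pH-extrapolation route only), `fit_slope`,
#'   `fit_intercept`, `n_points`, `r_squared`,
#'   `extrapolation_span_warning`, `qc_flags` (see [oecd_qc]), the
#'   underlying `lm` fit (`fit`) and the regression data (`data`).
#' @seealso [fit_method1], [fit_method2], [fit_logp_vs_conc] for the
#'   method-specific wrappers; [oecd_qc]; [simulate.biphasic_system] for
#'   generating validation data.
#' @examples
#' nap <- solute("naproxen", "acid", 4.18)
#' sys <- biphasic_system(P_neutral_0 = 10^3, conc_slope_s = 0)
#' ser <- simulate(sys, seed = 1, solute = nap, noise = noise_model(0, 0))
#' fit <- kow_fit(ser, method = "ph_extrapolation")
#' coef(fit); fit$log_value
#' @export
kow_fit <- function(series,
                    method = c("auto", "ph_extrapolation",
                               "conc_extrapolation")) {
  stopifnot(inherits(series, "measurement_series"))
  method <- match.arg(method)
  ionizable <- is_ionizable(series$solute)
  if (method == "auto") {
    method <- if (ionizable) "ph_extrapolation" else "conc_extrapolation"
  }
  d <- series$measurements
  if (nrow(d) < 3L) {
    stop("insufficient data: at least 3 measurements are required",
         call. = FALSE)
  }
  logD <- log_partition(d$c_org, d$c_aq)
  w <- fit_weights(d)

  if (method == "ph_extrapolation") {
    if (!ionizable) {
      stop(paste("pH extrapolation is unsupported for neutral solutes;",
                 "use the concentration extrapolation (fit_logp_vs_conc)"),
           call. = FALSE)
    }
    span <- diff(range(d$pH))
    if (span == 0) {
      stop("degenerate fit: all measurements share the same pH",
           call. = FALSE)
    }
    if (span <= 0.1) {
      warning("pH span <= 0.1 units; the extrapolation is ill conditioned",
              call. = FALSE)
    }
    dat <- data.frame(x = d$pH, y = logD)
    fit <- stats::lm(y ~ x, data = dat, weights = w)
    pr <- quiet_perfect_fit(
      stats::predict(fit, newdata = data.frame(x = 7), se.fit = TRUE))
    logDow <- unname(pr$fit)
    se <- unname(pr$se.fit)
    log_value <- logDow + ionization_correction(7, series$solute)
    span_warn <- min(abs(7 - d$pH)) > span
  } else {
    y <- if (ionizable) {
      logD + ionization_correction(d$pH, series$solute)
    } else logD
    if (length(unique(d$c_total)) < 3L) {
      stop("insufficient data: need >= 3 distinct overall concentrations",
           call. = FALSE)
    }
    dat <- data.frame(x = d$c_total, y = y)
    fit <- stats::lm(y ~ x, data = dat, weights = w)
    pr <- quiet_perfect_fit(
      stats::predict(fit, newdata = data.frame(x = 0), se.fit = TRUE))
    logDow <- NA_real_
    log_value <- unname(pr$fit)
    se <- unname(pr$se.fit)
    span_warn <- min(d$c_total) > diff(range(d$c_total))
  }
  cf <- stats::coef(fit)
  structure(list(
    method = method,
    solute = series$solute,
    log_value = log_value,
    std_error = se,
    intermediate_logDow = logDow,
    fit_slope = unname(cf[2L]),
    fit_intercept = unname(cf[1L]),
    n_points = nrow(d),
    r_squared = quiet_perfect_fit(summary(fit)$r.squared),
    extrapolation_span_warning = span_warn,
    qc_flags = oecd_qc(series),
    fit = fit,
    data = dat,
    series = series), class = "kow_fit")
}

# lm warns about "essentially perfect fit" on noise-free simulated data;
# that situation is legitimate here, so the specific warning is muffled
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# inverse-variance weights on the log10 scale from replicate sds, or NULL
fit_weights <- function(d) {
  if (all(is.finite(d$c_org_sd)) && all(is.finite(d$c_aq_sd)) &&
      all(d$c_org_sd > 0) && all(d$c_aq_sd > 0)) {
    v <- ((d$c_org_sd / d$c_org)^2 + (d$c_aq_sd / d$c_aq)^2) / log(10)^2
    1 / v
  } else NULL
}

#' Fit by pH extrapolation (Method 1)
#'
#' Wrapper for `kow_fit(series, method = "ph_extrapolation")`: regress log D
#' on the aqueous pH, extrapolate to pH 7 (log D_OW), convert to log K_OW.
#' Ionizable solutes only.
#'
#' @param series A [measurement_series].
#' @return A `kow_fit` object; see [kow_fit].
#' @export
fit_method1 <- function(series) kow_fit(series, "ph_extrapolation")

#' Fit by conversion and concentration extrapolation (Method 2)
#'
#' Wrapper for the concentration-extrapolation route for ionizable solutes:
#' convert each log D to log P with its own pH, regress log P on the overall
#' concentration, report the intercept at c = 0 as log K_OW.
#'
#' @param series A [measurement_series] of an ionizable solute.
#' @return A `kow_fit` object; see [kow_fit].
#' @export
fit_method2 <- function(series) {
  if (!is_ionizable(series$solute)) {
    stop(paste("method 2 applies to ionizable solutes;",
               "use fit_logp_vs_conc for neutral solutes"), call. = FALSE)
  }
  kow_fit(series, "conc_extrapolation")
}

#' Fit log P against concentration (neutral solutes)
#'
#' The only route available for nonionizable solutes, for which
#' log D = log P identically: regress log P on the overall concentration and
#' report the intercept. Called on an ionizable solute it warns (the pH- or
#' conversion-based methods are preferred) but proceeds on the converted
#' log P values.
#'
#' @param series A [measurement_series].
#' @return A `kow_fit` object; see [kow_fit].
#' @export
fit_logp_vs_conc <- function(series) {
  if (is_ionizable(series$solute)) {
    warning(paste("ionizable solute: proceeding on converted log P values;",
                  "fit_method1/fit_method2 are preferred"), call. = FALSE)
  }
  kow_fit(series, "conc_extrapolation")
}

#' Ordinary (optionally weighted) least-squares line fit
#'
#' Thin regression utility shared by the fitting routes: a straight line
#' through at least three points, with optional inverse-variance weights,
#' returning the slope, intercept, their standard errors and r-squared.
#'
#' @param xs,ys Numeric vectors of equal length >= 3; `xs` must not be
#'   constant.
#' @param weights Optional non-negative weights.
#' @return A list with `slope`, `intercept`, `se_slope`, `se_intercept`,
#'   `r_squared`.
#' @export
linear_fit <- function(xs, ys, weights = NULL) {
  stopifnot(is.numeric(xs), is.numeric(ys), length(xs) == length(ys))
  if (length(xs) < 3L) {
    stop("insufficient data: at least 3 points are required", call. = FALSE)
  }
  if (diff(range(xs)) == 0) {
    stop("degenerate fit: xs are constant", call. = FALSE)
  }
  fit <- stats::lm(ys ~ xs, weights = weights)
  sm <- quiet_perfect_fit(summary(fit))
  cf <- sm$coefficients
  list(slope = cf["xs", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       se_slope = cf["xs", "Std. Error"],
       se_intercept = cf["(Intercept)", "Std. Error"],
       r_squared = sm$r.squared)
}

method_label <- function(method) {
  switch(method,
         ph_extrapolation = "pH extrapolation to 7 (Method 1)",
         conc_extrapolation = "extrapolation to zero concentration (Method 2)",
         method)
}

#' @export
print.kow_fit <- function(x, digits = 4, ...) {
  cat(sprintf("log K_OW estimate for %s by %s\n", x$solute$name,
              method_label(x$method)))
  cat(sprintf("  log K_OW = %.*f  (se %.*f, n = %d, r^2 = %.4f)\n",
              digits, x$log_value, digits, x$std_error, x$n_points,
              x$r_squared))
  if (!is.na(x$intermediate_logDow)) {
    cat(sprintf("  intermediate log D_OW at pH 7 = %.*f\n", digits,
                x$intermediate_logDow))
  }
  invisible(x)
}

#' @export
summary.kow_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$fit)),
            class = "summary.kow_fit")
}

#' @export
print.summary.kow_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  fitted line: slope = %.*g, intercept = %.*g\n",
              digits, f$fit_slope, digits, f$fit_intercept))
  if (f$extrapolation_span_warning) {
    cat("  warning: extrapolation distance exceeds the data span\n")
  }
  nqc <- nrow(f$qc_flags)
  if (nqc > 0) {
    cat(sprintf("  OECD QC: %d measurement-phase value(s) above 0.01 mol/L\n",
                nqc))
  } else {
    cat("  OECD QC: all phase concentrations within 0.01 mol/L\n")
  }
  invisible(x)
}

#' @export
coef.kow_fit <- function(object, ...) {
  c(log_KOW = object$log_value, intercept = object$fit_intercept,
    slope = object$fit_slope)
}

#' @export
residuals.kow_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
confint.kow_fit <- function(object, parm = "log_KOW", level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$n_points - 2L)
  ci <- object$log_value + c(-1, 1) * tq * object$std_error
  m <- matrix(ci, nrow = 1,
              dimnames = list("log_KOW",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' Predict along the fitted extrapolation line
#'
#' For a pH-extrapolation fit, predicts log D at new pH values; for a
#' concentration-extrapolation fit, predicts log P at new overall
#' concentrations.
#'
#' @param object A `kow_fit`.
#' @param newdata Optional numeric vector of abscissa values (pH or
#'   c_total, depending on the method); defaults to the fitted data.
#' @param ... Passed to [stats::predict.lm].
#' @return Numeric vector of predictions.
#' @export
predict.kow_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  stopifnot(is.numeric(newdata))
  unname(stats::predict(object$fit, newdata = data.frame(x = newdata), ...))
}

#' Plot a log K_OW extrapolation fit
#'
#' Scatter of the regression data with the fitted line and the
#' extrapolation point (pH 7 or zero concentration) marked with a star.
#'
#' @param x A `kow_fit`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.kow_fit <- function(x, ...) {
  ph_method <- x$method == "ph_extrapolation"
  x0 <- if (ph_method) 7 else 0
  y0 <- if (ph_method) x$intermediate_logDow else x$log_value
  xl <- range(c(x$data$x, x0))
  yl <- range(c(x$data$y, y0))
  graphics::plot(x$data$x, x$data$y,
                 xlab = if (ph_method) "pH (aqueous phase)" else
                   "overall solute concentration / mol L^-1",
                 ylab = if (ph_method) "log D" else "log P",
                 xlim = xl, ylim = yl,
                 main = sprintf("%s: %s", x$solute$name,
                                method_label(x$method)), ...)
  graphics::abline(x$fit, lty = 2)
  graphics::points(x0, y0, pch = 8, cex = 1.5, col = 2)
  invisible(x)
}
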