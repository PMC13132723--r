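#' Three-parameter logistic recovery curve
#'
#' `recovery(day) = L / (1 + exp(-k * (day - t0)))`, the phenomenological
#' model of macrophage repopulation after CSF-1R-inhibitor withdrawal:
#' `L` is the asymptote (% of control), `k` the growth rate (per day) and
#' `t0` the inflection day.
#'
#' @param day numeric vector of days.
#' @param L,k,t0 curve parameters.
#' @return Recovery in % of control at each `day`.
#' @export
logistic_curve <- function(day, L, k, t0) L / (1 + exp(-k * (day - t0)))

# initialization per the fitting scheme: L from the observed plateau,
# t0 from the interpolated half-max crossing, k from the 25-75% rise time
logistic_inits <- function(days, y) {
  L0 <- min(max(max(y), 50), 150)
  half <- L0 / 2
  ord <- order(days)
  d <- days[ord]; yy <- y[ord]
  t0 <- if (any(yy >= half) && any(yy < half)) {
    i <- which(yy >= half)[1L]
    if (i == 1L) d[1L] else {
      d[i - 1L] + (half - yy[i - 1L]) / (yy[i] - yy[i - 1L]) * (d[i] - d[i - 1L])
    }
  } else stats::median(d)
  cross <- function(q) {
    i <- which(yy >= q * L0)[1L]
    if (is.na(i)) max(d) else d[i]
  }
  rise <- cross(0.75) - cross(0.25)
  k0 <- if (is.finite(rise) && rise > 0) 4 / rise else 0.5
  t0 <- min(max(t0, 0), max(d) + 30)
  k0 <- min(max(k0, 1e-3), 10)
  c(L = L0, k = k0, t0 = t0)
}

#' Fit the logistic repopulation model by nonlinear least squares
#'
#' Minimizes the residual sum of squares of
#' `recovery ~ L / (1 + exp(-k * (day - t0)))` over observed
#' (day, % recovery) points, typically the per-day mean recovery from
#' [recovery_curve()]. Fitting uses Levenberg-Marquardt least squares under
#' box constraints (`L` in (0, 200], `k` in (1e-4, 10], `t0` in
#' [0, max(day) + 30]) from a small multi-start lattice around data-driven
#' initial values; the best converged start wins. Failures never raise: the
#' returned object carries `converged = FALSE` and a `reason`.
#'
#' @param days numeric vector of distinct days (>= 3 points).
#' @param recovery_pct numeric vector of recovery values (% of control).
#' @param weights optional nonnegative weights (e.g. `1/se^2`); default
#'   unweighted.
#' @return An object of class `logistic_fit` with components `coefficients`
#'   (`L`, `k`, `t0`), `converged`, `reason`, `r_squared`, `residual_ss`,
#'   `n_points`, and the data. Methods: [print()], [summary()], [coef()],
#'   [predict.logistic_fit()], [fitted()], [residuals()],
#'   [plot.logistic_fit()].
#' @examples
#' d <- c(1, 5, 14, 56, 84, 182)
#' fit <- fit_logistic(d, logistic_curve(d, L = 100, k = 0.5, t0 = 8))
#' coef(fit)
#' t90(fit)
#' @seealso [t90()], [logistic_predict()], [fit_kinetics_report()]
#' @export
fit_logistic <- function(days, recovery_pct, weights = NULL) {
  days <- as.numeric(days); y <- as.numeric(recovery_pct)
  fail <- function(reason) {
    structure(list(coefficients = c(L = NA_real_, k = NA_real_, t0 = NA_real_),
                   converged = FALSE, reason = reason,
                   r_squared = NA_real_, residual_ss = NA_real_,
                   n_points = length(y),
                   data = data.frame(day = days, recovery_pct = y)),
              class = "logistic_fit")
  }
  if (length(days) != length(y)) stop("days and recovery_pct lengths differ")
  if (anyNA(days) || anyNA(y)) return(fail("missing values in data"))
  if (length(days) < 3L) return(fail("fewer than 3 points"))
  if (anyDuplicated(days)) stop("days must be distinct (aggregate to per-day means first)")
  if (stats::sd(y) == 0) return(fail("degenerate/flat data"))
  if (is.null(weights)) weights <- rep(1, length(y))

  init <- logistic_inits(days, y)
  starts <- list(
    init,
    c(init["L"], k = unname(init["k"]) / 4, init["t0"]),
    c(init["L"], k = min(unname(init["k"]) * 4, 10), init["t0"]),
    c(init["L"], init["k"], t0 = unname(init["t0"]) * 0.5),
    c(init["L"], init["k"], t0 = min(unname(init["t0"]) * 1.5 + 1, max(days) + 30))
  )
  lower <- c(L = 1e-6, k = 1e-4, t0 = 0)
  upper <- c(L = 200, k = 10, t0 = max(days) + 30)
  dat <- data.frame(day = days, y = y)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (day - t0))), data = dat,
                        start = as.list(st), weights = weights,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(fail("nonlinear least squares did not converge from any start"))
  cf <- stats::coef(best$fit)
  ss_tot <- sum((y - mean(y))^2)
  rss_plain <- sum((y - logistic_curve(days, cf["L"], cf["k"], cf["t0"]))^2)
  structure(list(coefficients = c(L = unname(cf["L"]), k = unname(cf["k"]),
                                  t0 = unname(cf["t0"])),
                 converged = TRUE, reason = NA_character_,
                 r_squared = 1 - rss_plain / ss_tot, residual_ss = rss_plain,
                 n_points = length(y),
                 data = data.frame(day = days, recovery_pct = y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("Logistic repopulation fit: recovery = L / (1 + exp(-k (day - t0)))\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$reason, "\n")
  } else {
    cf <- x$coefficients
    cat(sprintf("  L  = %s %% of control\n  k  = %s per day\n  t0 = %s days\n",
                format(cf["L"], digits = digits),
                format(cf["k"], digits = digits),
                format(cf["t0"], digits = digits)))
    cat(sprintf("  R-squared = %s on %d points\n",
                format(x$r_squared, digits = digits), x$n_points))
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
summary.logistic_fit <- function(object, ...) {
  t90r <- if (object$converged) t90(object) else NULL
  out <- list(fit = object, t90 = t90r)
  class(out) <- "summary.logistic_fit"
  out
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$t90)) {
    if (x$t90$defined) {
      cat(sprintf("  t90 (day the curve reaches %g%% of control) = %.4g days\n",
                  x$t90$threshold, x$t90$t90_days))
    } else cat("  t90 undefined:", x$t90$reason, "\n")
  }
  invisible(x)
}

#' Predict recovery from a converged logistic fit
#'
#' @param object a converged `logistic_fit`.
#' @param newdata optional data frame with a `day` column, or numeric days via
#'   `day`; defaults to the fitted days.
#' @param day numeric vector of days (alternative to `newdata`).
#' @param ... unused.
#' @return Predicted recovery (% of control).
#' @export
predict.logistic_fit <- function(object, newdata = NULL, day = NULL, ...) {
  if (!object$converged) {
    stop("cannot predict from a non-converged fit (", object$reason, ")")
  }
  if (is.null(day)) {
    day <- if (is.null(newdata)) object$data$day else newdata$day
  }
  cf <- object$coefficients
  unname(logistic_curve(day, cf["L"], cf["k"], cf["t0"]))
}

#' Evaluate a fitted logistic curve at given days
#'
#' Functional alias of [predict.logistic_fit()]; refuses non-converged fits.
#'
#' @param fit a converged `logistic_fit`.
#' @param day numeric vector of days.
#' @return Recovery (% of control) at `day`.
#' @export
logistic_predict <- function(fit, day) predict(fit, day = day)

#' @export
fitted.logistic_fit <- function(object, ...) predict(object)

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$recovery_pct - fitted(object)
}

#' Plot a logistic recovery fit
#'
#' Observed per-day recovery points with the fitted curve and the 90%
#' threshold line; base graphics.
#'
#' @param x a `logistic_fit`.
#' @param threshold recovery threshold line to draw (% of control).
#' @param ... passed to [graphics::plot()].
#' @export
plot.logistic_fit <- function(x, threshold = 90, ...) {
  graphics::plot(x$data$day, x$data$recovery_pct, xlab = "day",
                 ylab = "recovery (% of control)", ...)
  if (x$converged) {
    dd <- seq(min(x$data$day), max(x$data$day), length.out = 200)
    graphics::lines(dd, predict(x, day = dd))
    graphics::abline(h = threshold, lty = 3)
    tr <- t90(x, threshold)
    if (tr$defined) graphics::abline(v = tr$t90_days, lty = 3)
  }
  invisible(x)
}

#' Analytic time to a recovery threshold (t90)
#'
#' Solves `L / (1 + exp(-k (t - t0))) = threshold` for `t`:
#' \deqn{t_{90} = t_0 - (1/k)\, \ln(L/\mathrm{threshold} - 1)}
#' The threshold is an absolute % of control (90 by default), not a fraction
#' of the asymptote. Undefined (never `NaN`) when the asymptote does not
#' exceed the threshold or `k <= 0`.
#'
#' @param fit a converged `logistic_fit`, or a named numeric vector
#'   `c(L = , k = , t0 = )` of curve parameters.
#' @param threshold recovery threshold in % of control (default 90).
#' @return A list of class `t90_result`: `defined`, `t90_days` (when
#'   defined), `reason` (when not), `threshold`.
#' @examples
#' t90(c(L = 100, k = log(9), t0 = 5))  # exactly day 6
#' @export
t90 <- function(fit, threshold = 90) {
  if (inherits(fit, "logistic_fit")) {
    if (!fit$converged) {
      stop("t90 requires a converged fit (", fit$reason, ")")
    }
    cf <- fit$coefficients
  } else {
    cf <- fit
    if (!all(c("L", "k", "t0") %in% names(cf))) {
      stop("fit must be a logistic_fit or a named vector c(L=, k=, t0=)")
    }
  }
  undef <- function(reason) {
    structure(list(defined = FALSE, t90_days = NA_real_, reason = reason,
                   threshold = threshold), class = "t90_result")
  }
  if (!is.finite(threshold) || threshold <= 0) {
    return(undef("threshold must be a positive recovery level"))
  }
  if (!is.finite(cf["k"]) || cf["k"] <= 0) return(undef("growth rate k is not positive"))
  if (!is.finite(cf["L"]) || cf["L"] <= threshold) {
    return(undef("asymptote below threshold"))
  }
  structure(list(defined = TRUE,
                 t90_days = unname(cf["t0"] - log(cf["L"] / threshold - 1) / cf["k"]),
                 reason = NA_character_, threshold = threshold),
            class = "t90_result")
}

#' @export
print.t90_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("t%g = %.4g days\n", x$threshold, x$t90_days))
  } else cat(sprintf("t%g undefined: %s\n", x$threshold, x$reason))
  invisible(x)
}

#' Per-stratum kinetics report: recovery, logistic fit, t90 and Welch scan
#'
#' Runs the full pipeline for each (region, cell type) stratum of a density
#' table: percent-of-control recovery per day, logistic fit to the per-day
#' mean recovery, analytic time-to-threshold, and the per-day Welch tests
#' with Bonferroni correction. Strata whose fit fails to converge are
#' included with flags rather than dropped.
#'
#' @param table a `DensityTable` data frame.
#' @param strata data frame with columns `region`, `cell_type`; defaults to
#'   all strata present in `table`.
#' @param threshold t90 recovery threshold (% of control).
#' @param m Bonferroni comparisons (default: number of tested days).
#' @param control control pooling policy, see [recovery_curve()].
#' @return An object of class `kinetics_report`: list with `summary` (one row
#'   per stratum: parameters, R-squared, convergence, t90), `tests` (stacked
#'   Welch/Bonferroni results) and `curves` (stacked recovery estimates).
#' @export
fit_kinetics_report <- function(table, strata = NULL, threshold = 90, m = NULL,
                                control = c("pooled", "per_day")) {
  control <- match.arg(control)
  if (is.null(strata)) {
    strata <- unique(table[table$group == "treated", c("region", "cell_type")])
  }
  strata <- as.data.frame(strata)
  if (nrow(strata) == 0L) stop("empty strata list")
  strata <- strata[order(strata$region, strata$cell_type), , drop = FALSE]
  summ <- list(); tests <- list(); curves <- list()
  for (i in seq_len(nrow(strata))) {
    reg <- strata$region[i]; ct <- strata$cell_type[i]
    crv <- recovery_curve(table, reg, ct, control = control)
    fit <- fit_logistic(crv$day, crv$recovery_pct)
    tr <- if (fit$converged) t90(fit, threshold) else {
      structure(list(defined = FALSE, t90_days = NA_real_,
                     reason = paste("fit not converged:", fit$reason),
                     threshold = threshold), class = "t90_result")
    }
    wt <- welch_bonferroni_scan(table, reg, ct, m = m, control = control)
    summ[[i]] <- data.frame(
      region = reg, cell_type = ct,
      L = fit$coefficients["L"], k = fit$coefficients["k"],
      t0 = fit$coefficients["t0"], r_squared = fit$r_squared,
      converged = fit$converged,
      reason = if (fit$converged) NA_character_ else fit$reason,
      t90_defined = tr$defined, t90_days = tr$t90_days,
      t90_threshold = threshold, n_days = fit$n_points,
      row.names = NULL)
    tests[[i]] <- cbind(data.frame(region = reg, cell_type = ct), wt)
    curves[[i]] <- crv
  }
  structure(list(summary = do.call(rbind, summ),
                 tests = do.call(rbind, tests),
                 curves = do.call(rbind, curves),
                 control = control),
            class = "kinetics_report")
}

#' @export
print.kinetics_report <- function(x, digits = 4, ...) {
  cat("Repopulation kinetics report (", nrow(x$summary), " strata, controls ",
      x$control, ")\n", sep = "")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
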