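#' Concentration time series
#'
#' Container for an observed (or synthetic) water-column metal
#' concentration series.
#'
#' @param time_d Sample times (d), strictly increasing.
#' @param conc_ug_L Concentrations (ug/L), >= 0.
#' @param phase `"dissolved"` or `"total"`.
#' @param below_dl Logical vector flagging samples at/below the detection
#'   limit (excluded from fits); defaults to all `FALSE`.
#' @return An object of class `cu_timeseries` (also a data frame).
#' @export
time_series <- function(time_d, conc_ug_L,
                        phase = c("dissolved", "total"),
                        below_dl = NULL) {
  phase <- match.arg(phase)
  if (length(time_d) != length(conc_ug_L)) {
    stop("time_d and conc_ug_L must have equal length", call. = FALSE)
  }
  if (any(diff(time_d) <= 0)) {
    stop("time_d must be strictly increasing", call. = FALSE)
  }
  if (any(conc_ug_L < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  below_dl <- below_dl %||% rep(FALSE, length(time_d))
  ts <- data.frame(time_d = time_d, conc_ug_L = conc_ug_L,
                   below_dl = as.logical(below_dl))
  attr(ts, "phase") <- phase
  class(ts) <- c("cu_timeseries", "data.frame")
  ts
}

#' Fit a first-order loss model to a concentration series
#'
#' Fits C(t) = C0 exp(-k t). The default method is ordinary least squares
#' on ln C versus t (k = -slope, 95 % CI from the slope's t interval);
#' `"nonlinear"` refits on the untransformed scale by Levenberg-Marquardt
#' least squares with a Wald interval. Samples flagged below the detection
#' limit, and zero/negative concentrations, are excluded (with a warning
#' for the latter). The fit is marked unsupported when the interval for k
#' includes zero or negative values, i.e. when the upper confidence limit
#' of the regression slope indicates an increase in concentration.
#'
#' @param series A [time_series()] (or data frame with `time_d`,
#'   `conc_ug_L` and optionally `below_dl`).
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return An object of class `first_order_fit`: `k_per_d`, `k_ci95`
#'   (lower, upper), `c0_ug_L`, `n_points`, `method`, `supported`.
#' @export
fit_first_order <- function(series, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  dat <- as.data.frame(series)
  if (is.null(dat$below_dl)) dat$below_dl <- FALSE
  drop_dl <- dat$below_dl
  drop_np <- dat$conc_ug_L <= 0
  if (any(drop_np & !drop_dl)) {
    warning(sum(drop_np & !drop_dl),
            " zero/negative concentration(s) excluded from fit",
            call. = FALSE)
  }
  dat <- dat[!(drop_dl | drop_np), , drop = FALSE]
  if (nrow(dat) < 3) {
    stop("need at least 3 usable points with positive concentration",
         call. = FALSE)
  }

  ll <- stats::lm(log(conc_ug_L) ~ time_d, data = dat)
  k_ll <- -unname(stats::coef(ll)[2])
  c0_ll <- exp(unname(stats::coef(ll)[1]))
  ci_sl <- suppressWarnings(stats::confint(ll, "time_d", level = 0.95))
  k_ci <- sort(-as.numeric(ci_sl))
  if (any(!is.finite(k_ci))) k_ci <- c(k_ll, k_ll)

  if (method == "loglinear") {
    k <- k_ll
    c0 <- c0_ll
  } else {
    nl <- minpack.lm::nlsLM(
      conc_ug_L ~ c0 * exp(-k * time_d), data = dat,
      start = list(c0 = c0_ll, k = k_ll))
    est <- summary(nl)$coefficients
    k <- est["k", "Estimate"]
    c0 <- est["c0", "Estimate"]
    half <- stats::qt(0.975, df = nrow(dat) - 2) * est["k", "Std. Error"]
    k_ci <- c(k - half, k + half)
  }

  structure(list(k_per_d = k, k_ci95 = k_ci, c0_ug_L = c0,
                 n_points = nrow(dat), method = method,
                 supported = is.finite(k_ci[1]) && k_ci[1] > 0),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf(
    "<first_order_fit> k = %.4g 1/d (95%% CI %.4g-%.4g), C0 = %.4g ug/L\n",
    x$k_per_d, x$k_ci95[1], x$k_ci95[2], x$c0_ug_L))
  cat("  n =", x$n_points, "| method:", x$method,
      "| first-order structure supported:", x$supported, "\n")
  invisible(x)
}

#' Removal times from a fitted first-order rate
#'
#' t_x = ln(100/x)/k, with 95 % bounds propagated antitonically from the
#' rate-constant interval: the lower time bound uses the upper k bound and
#' vice versa.
#'
#' @param fit A `first_order_fit`, or a bare positive rate constant
#'   (1/d), in which case no interval is attached.
#' @return A [removal_times()] record (method `"fit"`); when k <= 0 the
#'   times are `NA` with an explanatory note.
#' @examples
#' removal_times_from_fit(0.0091)  # published MELIMEX loss rate
#' @export
removal_times_from_fit <- function(fit) {
  if (is.numeric(fit)) {
    fit <- list(k_per_d = fit, k_ci95 = c(NA_real_, NA_real_),
                supported = fit > 0)
  }
  k <- fit$k_per_d
  if (!is.finite(k) || k <= 0) {
    return(removal_times(NA_real_, NA_real_, method = "fit",
                         note = "non-positive rate constant"))
  }
  tx <- function(x) log(100 / x) / k
  ci <- function(x) {
    lo <- log(100 / x) / fit$k_ci95[2]
    hi <- if (is.na(fit$k_ci95[1]) || fit$k_ci95[1] <= 0) {
      Inf
    } else {
      log(100 / x) / fit$k_ci95[1]
    }
    if (is.na(fit$k_ci95[2])) c(NA_real_, NA_real_) else c(lo, hi)
  }
  removal_times(tx(50), tx(30), t50_ci = ci(50), t70_ci = ci(30),
                method = "fit")
}

#' Interpolated removal times from a raw series
#'
#' Fallback used when the first-order model is unsupported: the fraction
#' remaining is computed relative to the post-dose maximum and the removal
#' time is the first downward crossing of x/100, linearly interpolated
#' between bracketing samples. With a non-monotone series the first
#' crossing is returned and a multiplicity warning is raised.
#'
#' @param series A [time_series()].
#' @param x_percent_remaining Thresholds to report; the default covers the
#'   conventional half-time (50) and 70 % removal (30).
#' @return A [removal_times()] record (method `"interpolation"`);
#'   thresholds never crossed give `NA` plus a note.
#' @export
interpolate_removal_time <- function(series,
                                     x_percent_remaining = c(50, 30)) {
  dat <- as.data.frame(series)
  if (max(dat$conc_ug_L) <= 0) {
    stop("series has no positive post-dose maximum", call. = FALSE)
  }
  i0 <- which.max(dat$conc_ug_L)
  tt <- dat$time_d[i0:nrow(dat)] - dat$time_d[i0]
  frac <- dat$conc_ug_L[i0:nrow(dat)] / dat$conc_ug_L[i0]

  one <- function(x) {
    lev <- x / 100
    below <- frac <= lev
    if (any(below)) {
      runs <- rle(below)
      if (sum(runs$values) > 1) {
        warning("multiple crossings of the ", x,
                "% level; first crossing returned", call. = FALSE)
      }
    }
    first_crossing(tt, frac, lev)
  }
  res <- vapply(sort(x_percent_remaining, decreasing = TRUE), one,
                numeric(1))
  t50 <- res[1]
  t70 <- if (length(res) > 1) res[2] else NA_real_
  note <- NULL
  span <- max(tt)
  if (is.na(t70)) note <- sprintf("70%% removal not observed in %g d", span)
  if (is.na(t50)) note <- sprintf("50%% removal not observed in %g d", span)
  removal_times(t50, t70, method = "interpolation", note = note)
}

#' Summarise removal times for a collection of series
#'
#' Produces one record per named system: duplicate series (e.g. paired
#' microcosms) are first averaged arithmetically on their common sampling
#' grid; a first-order fit is used when its structure is supported, and
#' interpolation from the fraction-remaining curve otherwise.
#'
#' @param collection Named list; each element is a [time_series()] or an
#'   unnamed list of replicate [time_series()] objects sharing a grid.
#' @return A data frame with columns `system`, `method`, `t50_d`,
#'   `t50_lo`, `t50_hi`, `t70_d`, `t70_lo`, `t70_hi`, `note`.
#' @export
removal_summary <- function(collection) {
  stopifnot(length(names(collection)) == length(collection))
  rows <- lapply(names(collection), function(nm) {
    el <- collection[[nm]]
    if (!inherits(el, "cu_timeseries") && is.list(el) &&
        !is.data.frame(el)) {
      tmpl <- el[[1]]
      for (r in el[-1]) {
        if (!isTRUE(all.equal(r$time_d, tmpl$time_d))) {
          stop("replicate series for '", nm,
               "' must share a sampling grid", call. = FALSE)
        }
      }
      conc <- rowMeans(vapply(el, function(r) r$conc_ug_L,
                              numeric(nrow(tmpl))))
      el <- time_series(tmpl$time_d, conc,
                        phase = attr(tmpl, "phase") %||% "dissolved")
    }
    fit <- tryCatch(fit_first_order(el), error = function(e) NULL)
    rt <- if (!is.null(fit) && fit$supported) {
      removal_times_from_fit(fit)
    } else {
      interpolate_removal_time(el)
    }
    data.frame(system = nm, method = rt$method,
               t50_d = rt$t50_d, t50_lo = rt$t50_ci[1],
               t50_hi = rt$t50_ci[2],
               t70_d = rt$t70_d, t70_lo = rt$t70_ci[1],
               t70_hi = rt$t70_ci[2],
               note = rt$note %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
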