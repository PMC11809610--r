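# Hill-equation modeling of cumulative apoptosis fractions over time.

#' Hill apoptosis-dynamics parameters
#'
#' @param p_min,p_max Minimal and maximal apoptotic fractions,
#'   `0 <= p_min <= p_max <= 1`.
#' @param t_half Characteristic half-time in hours, `> 0`.
#' @param n Hill (cooperativity) coefficient, `> 0`.
#' @return A `hill_params` object.
#' @export
hill_params <- function(p_min, p_max, t_half, n) {
  stopifnot(p_min >= 0, p_max >= p_min, p_max <= 1, t_half > 0, n > 0)
  structure(list(p_min = p_min, p_max = p_max, t_half = t_half, n = n),
            class = "hill_params")
}

#' Hill model of the apoptotic fraction over time
#'
#' \eqn{P(t) = P_{max} - (P_{max} - P_{min}) / (1 + (t/t_{half})^n)}:
#' sigmoidal growth from `p_min` at t = 0 to `p_max`, reaching the
#' midpoint at `t_half`; `n` sets how switch-like the transition is.
#'
#' @param t Times in hours, `>= 0`.
#' @param params A [hill_params()] object.
#' @return Apoptotic fraction(s).
#' @export
hill_model <- function(t, params) {
  stopifnot(inherits(params, "hill_params"), all(t >= 0))
  params$p_max - (params$p_max - params$p_min) /
    (1 + (t / params$t_half)^params$n)
}

#' Apoptosis event-time series
#'
#' @param event_times Death times in hours of the cells that underwent
#'   apoptosis (non-negative).
#' @param n_total Total number of observed cells (`>=` number of events).
#' @param censor_time End of the observation window in hours.
#' @return An `apoptosis_series` object.
#' @export
apoptosis_series <- function(event_times, n_total,
                             censor_time = max(event_times, 0)) {
  stopifnot(all(event_times >= 0), n_total >= length(event_times),
            censor_time >= 0)
  structure(list(event_times = sort(as.numeric(event_times)),
                 n_total = as.integer(n_total),
                 censor_time = censor_time),
            class = "apoptosis_series")
}

#' Cumulative apoptotic fraction
#'
#' Right-continuous step function: the fraction of all observed cells
#' that died at or before each time.
#'
#' @param series An [apoptosis_series()].
#' @param times Evaluation times in hours (default: the event times).
#' @return A data.frame with `time_h` and `fraction`.
#' @export
cumulative_fraction <- function(series, times = NULL) {
  stopifnot(inherits(series, "apoptosis_series"))
  if (is.null(times)) times <- unique(series$event_times)
  frac <- vapply(times, function(t) sum(series$event_times <= t), 0) /
    series$n_total
  data.frame(time_h = times, fraction = frac)
}

#' Fit the Hill model to cumulative apoptosis data
#'
#' Weighted least squares on the cumulative fraction curve evaluated per
#' frame interval, with binomial-variance weights
#' `n_total / (p~ (1 - p~))` using a continuity-adjusted fraction so
#' empty and saturated time points keep finite weight. Parameters are
#' fitted on transformed scales that enforce
#' `0 <= p_min <= p_max <= 1`, `t_half > 0`, `n > 0`. A series without
#' events returns a flat fit (`p_max ~ p_min`) with a warning.
#'
#' @param series An [apoptosis_series()].
#' @param frame_h Frame interval in hours used to grid the cumulative
#'   curve (default 0.25, i.e. 15-min time lapse).
#' @param start Optional [hill_params()] start values.
#' @return A list with `params` ([hill_params()]), `se` (approximate
#'   standard errors on the natural scale, delta method), `converged`,
#'   and `data` (the fitted cumulative curve).
#' @export
fit_hill <- function(series, frame_h = 0.25, start = NULL) {
  stopifnot(inherits(series, "apoptosis_series"))
  n_events <- length(series$event_times)
  t_end <- max(series$censor_time, series$event_times, frame_h)
  times <- seq(frame_h, t_end, by = frame_h)
  cf <- cumulative_fraction(series, times)
  if (n_events == 0) {
    warning("no apoptosis events: returning a flat fit")
    return(list(params = hill_params(0, 1e-6, t_half = t_end, n = 1),
                se = NULL, converged = FALSE, data = cf))
  }
  if (length(unique(series$event_times)) < 5)
    stop("need events at 5 or more distinct time points")
  n <- series$n_total
  p_adj <- (cf$fraction * n + 0.5) / (n + 1)
  w <- n / (p_adj * (1 - p_adj))
  if (is.null(start)) {
    pmax0 <- min(max(n_events / n, 0.05), 0.99)
    start <- hill_params(1e-3, pmax0,
                         t_half = max(median(series$event_times), frame_h),
                         n = 2)
  }
  # theta: qlogis(p_min-ish), qlogis(p_max), log t_half, log n
  pack <- function(pp) c(qlogis(max(pp$p_min, 1e-6) / max(pp$p_max, 1e-5)),
                         qlogis(min(max(pp$p_max, 1e-6), 1 - 1e-9)),
                         log(pp$t_half), log(pp$n))
  unpack <- function(th) {
    p_max <- plogis(th[2])
    hill_params(plogis(th[1]) * p_max, p_max, exp(th[3]), exp(th[4]))
  }
  resid_fn <- function(th)
    sqrt(w) * (hill_model(cf$time_h, unpack(th)) - cf$fraction)
  fit <- nls.lm(par = pack(start), fn = resid_fn,
                control = nls.lm.control(maxiter = 500))
  params <- unpack(fit$par)
  se <- NULL
  dof <- max(length(cf$time_h) - 4, 1)
  # ridge the hessian: parameters at their boundary have zero curvature
  # on the transformed scale, and the delta-method jacobian collapses
  # their (inflated) variance back to ~0 on the natural scale
  hess <- fit$hessian
  diag(hess) <- diag(hess) + 1e-8 * max(diag(hess), 1)
  cv <- try(fit$deviance / dof * solve(hess), silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv)))) {
    th <- fit$par
    p_max <- plogis(th[2])
    d_pmax <- p_max * (1 - p_max)
    d_pmin_d1 <- plogis(th[1]) * (1 - plogis(th[1])) * p_max
    d_pmin_d2 <- plogis(th[1]) * d_pmax
    jac <- rbind(c(d_pmin_d1, d_pmin_d2, 0, 0),
                 c(0, d_pmax, 0, 0),
                 c(0, 0, exp(th[3]), 0),
                 c(0, 0, 0, exp(th[4])))
    vn <- jac %*% cv %*% t(jac)
    se <- setNames(sqrt(pmax(diag(vn), 0)),
                   c("p_min", "p_max", "t_half", "n"))
  }
  list(params = params, se = se, converged = fit$info %in% 1:4, data = cf)
}
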