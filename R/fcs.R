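# Two-component fluorescence correlation spectroscopy: a cytoplasmic and
# a membrane diffusion term in a 3D Gaussian focus, no triplet/bunching
# term (omitting it stabilizes fits of noisy live-cell curves without
# biasing the diffusion times).

#' Two-component FCS model parameters
#'
#' @param rho_cp,rho_mem Correlation amplitudes of the cytoplasmic and
#'   membrane species, `>= 0`.
#' @param tdiff_cp,tdiff_mem Diffusion times in ms, `> 0`.
#' @param kappa Focus aspect ratio z0/w0, `>= 1`.
#' @param ginf Residual correlation offset at infinite lag.
#' @return An `fcs_params` object.
#' @export
fcs_params <- function(rho_cp, rho_mem, tdiff_cp, tdiff_mem,
                       kappa = 5, ginf = 0) {
  stopifnot(rho_cp >= 0, rho_mem >= 0, tdiff_cp > 0, tdiff_mem > 0,
            kappa >= 1)
  structure(list(rho_cp = rho_cp, rho_mem = rho_mem,
                 tdiff_cp = tdiff_cp, tdiff_mem = tdiff_mem,
                 kappa = kappa, ginf = ginf),
            class = "fcs_params")
}

.fcs_component <- function(tc, rho, tdiff, kappa) {
  rho / ((1 + tc / tdiff) * sqrt(1 + tc / (kappa^2 * tdiff)))
}

#' Two-component FCS correlation model
#'
#' \eqn{G(t_c) = 1 + \sum_s \rho_s (1 + t_c/t_s)^{-1}
#' (1 + t_c/(\kappa^2 t_s))^{-1/2} + G_\infty} over the cytoplasmic and
#' membrane species. In the limit \eqn{\kappa \to \infty} the axial
#' factor tends to 1 and the model reduces to pure 2D diffusion.
#'
#' @param tc Lag times (same unit as the diffusion times, ms by
#'   convention here).
#' @param params An [fcs_params()] object.
#' @return Model correlation amplitudes G(tc).
#' @export
fcs_model <- function(tc, params) {
  stopifnot(inherits(params, "fcs_params"), all(tc >= 0))
  1 + .fcs_component(tc, params$rho_cp, params$tdiff_cp, params$kappa) +
    .fcs_component(tc, params$rho_mem, params$tdiff_mem, params$kappa) +
    params$ginf
}

#' Correlation curve container
#'
#' @param lag_ms Strictly increasing lag times in ms.
#' @param G Correlation amplitudes.
#' @param stderr Per-point standard errors (chunk-based weighting).
#' @param n_chunks Number of measurement chunks the errors derive from.
#' @return A `correlation_curve` object (a data.frame with attributes).
#' @export
correlation_curve <- function(lag_ms, G, stderr = NULL, n_chunks = NA) {
  stopifnot(all(diff(lag_ms) > 0))
  df <- data.frame(lag_ms = lag_ms, G = G,
                   stderr = if (is.null(stderr)) NA_real_ else stderr)
  attr(df, "n_chunks") <- n_chunks
  class(df) <- c("correlation_curve", "data.frame")
  df
}

#' Fit the two-component FCS model to one or more curves
#'
#' Weighted least squares (weights `1/stderr^2` when standard errors are
#' present) with the Levenberg-Marquardt algorithm. Diffusion times are
#' fitted on a log scale; amplitudes and the offset are free per curve.
#' With `global = TRUE` the two diffusion times are shared across all
#' curves (per-curve amplitudes stay free), the scheme used to pin the
#' membrane diffusion time on reference cells. `fix_membrane_time` clamps
#' the membrane diffusion time instead of fitting it (0.60 ms is the
#' reference value carried over to routine fits).
#'
#' @param curves A [correlation_curve()] or list of them (each with at
#'   least 8 lag points).
#' @param start An [fcs_params()] with start values.
#' @param fix_membrane_time Optional fixed membrane diffusion time in ms
#'   (e.g. 0.60); `NULL` fits it.
#' @param global Share diffusion times across curves (default FALSE).
#' @param kappa Focus aspect ratio, fixed from calibration (default from
#'   `start`).
#' @return A list with `params` (list of [fcs_params()], one per curve),
#'   `converged`, and `deviance`.
#' @export
fit_fcs <- function(curves, start = fcs_params(0.5, 0.5, 0.05, 0.6),
                    fix_membrane_time = NULL, global = FALSE,
                    kappa = start$kappa) {
  if (inherits(curves, "correlation_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  for (cv in curves)
    if (nrow(cv) < 8) stop("each curve needs at least 8 lag points")
  nc <- length(curves)
  wts <- lapply(curves, function(cv) {
    se <- cv$stderr
    if (all(is.na(se))) return(rep(1, nrow(cv)))
    se <- pmax(se, max(se, na.rm = TRUE) * 1e-3)
    1 / se^2
  })
  fix_mem <- !is.null(fix_membrane_time)
  shared <- global || nc == 1
  # parameter layout: per-curve (rho_cp, rho_mem, ginf); shared or
  # per-curve log diffusion times
  n_times <- if (fix_mem) 1 else 2
  n_time_blocks <- if (shared) 1 else nc
  unpack <- function(p, i) {
    amp <- p[(i - 1) * 3 + 1:3]
    tb <- 3 * nc + (if (shared) 0 else (i - 1) * n_times)
    tcp <- exp(p[tb + 1])
    tmem <- if (fix_mem) fix_membrane_time else exp(p[tb + 2])
    fcs_params(max(amp[1], 0), max(amp[2], 0), tcp, tmem,
               kappa = kappa, ginf = amp[3])
  }
  resid_fn <- function(p) {
    unlist(lapply(seq_len(nc), function(i) {
      pr <- unpack(p, i)
      sqrt(wts[[i]]) * (fcs_model(curves[[i]]$lag_ms, pr) - curves[[i]]$G)
    }))
  }
  p0 <- c(rep(c(start$rho_cp, start$rho_mem, start$ginf), nc),
          rep(c(log(start$tdiff_cp),
                if (!fix_mem) log(start$tdiff_mem)), n_time_blocks))
  fit <- nls.lm(par = p0, fn = resid_fn,
                control = nls.lm.control(maxiter = 500, ftol = 1e-12))
  params <- lapply(seq_len(nc), function(i) unpack(fit$par, i))
  list(params = if (nc == 1) params[[1]] else params,
       converged = fit$info %in% 1:4, deviance = fit$deviance)
}

#' Diffusion coefficient from a diffusion time
#'
#' `D = w0^2 / (4 t_diff)` for a focus of lateral 1/e^2 radius `w0`.
#'
#' @param tdiff_ms Diffusion time in ms.
#' @param omega0_um Focal radius in micrometers.
#' @return D in square micrometers per second.
#' @export
diffusion_coefficient <- function(tdiff_ms, omega0_um) {
  stopifnot(all(tdiff_ms > 0), omega0_um > 0)
  omega0_um^2 / (4 * tdiff_ms * 1e-3)
}

#' Focal radius from a reference diffusion standard
#'
#' Inverts [diffusion_coefficient()] for calibration against a dye of
#' known D (Rhodamine 110: 430 um^2/s at 22.5 C, 600 um^2/s at 37 C).
#'
#' @param tdiff_ms Measured diffusion time of the standard in ms.
#' @param D_um2_s Reference diffusion coefficient (default 430).
#' @return Focal radius omega0 in micrometers.
#' @export
calibrate_focal_radius <- function(tdiff_ms, D_um2_s = 430) {
  stopifnot(tdiff_ms > 0, D_um2_s > 0)
  sqrt(4 * D_um2_s * tdiff_ms * 1e-3)
}

#' Simulate a chunk-averaged FCS correlation curve
#'
#' Draws `n_chunks` noisy realizations of the model curve (Gaussian
#' per-point noise proportional to the correlation amplitude above
#' baseline, plus a small floor so tail points keep finite weight) and
#' returns their mean with standard-error weights, the chunk-based
#' weighting scheme used for measured curves. Seeded and reproducible.
#'
#' @param params An [fcs_params()].
#' @param lag_ms Lag-time grid in ms (default 96 log-spaced points,
#'   1e-3 to 1e3 ms).
#' @param n_chunks Number of chunks (default 15, `>= 2`).
#' @param noise Relative chunk noise level (default 0.01); 0 returns the
#'   exact model with zero errors.
#' @param seed Optional integer seed.
#' @return A [correlation_curve()].
#' @export
simulate_fcs_curve <- function(params, lag_ms = 10^seq(-3, 3, length.out = 96),
                               n_chunks = 15, noise = 0.01, seed = NULL) {
  stopifnot(n_chunks >= 2)
  if (!is.null(seed)) set.seed(seed)
  g <- fcs_model(lag_ms, params)
  amp0 <- params$rho_cp + params$rho_mem
  sdv <- noise * (pmax(g - 1 - params$ginf, 0) + 0.02 * amp0)
  chunks <- replicate(n_chunks, g + rnorm(length(g), 0, sdv))
  correlation_curve(lag_ms, rowMeans(chunks),
                    stderr = apply(chunks, 1, sd) / sqrt(n_chunks),
                    n_chunks = n_chunks)
}
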