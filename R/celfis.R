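# CELFIS: whole-cell integrated decay pattern fitting. The donor decay
# pattern, FRET rates and anisotropy calibration are frozen once, then
# single-cell fits free only x_FRET, one depolarization time and the
# overall amplitude, which keeps the cross-talk between x_FRET and the
# other parameters minimal.

#' Frozen pattern library for single-cell x_FRET fits
#'
#' @param donor A calibrated [donor_pattern()].
#' @param fret_rates List with `k` (FRET rate constants, 1/ns) and `a`
#'   (amplitudes summing to 1).
#' @param aniso An [anisotropy_pattern()] (fundamental anisotropy,
#'   depolarization time start value, G factor).
#' @return A `pattern_library` object.
#' @seealso [default_pattern_library()] for the calibrated defaults.
#' @export
pattern_library <- function(donor, fret_rates, aniso) {
  stopifnot(inherits(donor, "donor_pattern"),
            inherits(aniso, "anisotropy_pattern"),
            is.list(fret_rates), all(c("k", "a") %in% names(fret_rates)))
  if (abs(sum(fret_rates$a) - 1) > 1e-8)
    stop("FRET amplitudes must sum to 1")
  structure(list(donor = donor, fret_rates = fret_rates, aniso = aniso),
            class = "pattern_library")
}

.softmax <- function(z) {
  e <- exp(c(z, 0) - max(z, 0))
  e / sum(e)
}

# analytic weighted-LS amplitude of a unit-shape model
.ls_amplitude <- function(counts, shape, weights) {
  keep <- weights > 0 & shape > 0
  a <- sum(counts[keep] * shape[keep] / weights[keep]) /
    sum(shape[keep]^2 / weights[keep])
  max(a, 0)
}

#' Joint donor-pattern calibration fit
#'
#' Fits a common multi-exponential donor decay to a set of donor-only VM
#' histograms (typically 100-200 ROIs; at least 2) by weighted least
#' squares, with a shared lifetime/fraction pattern and per-decay free
#' amplitudes solved analytically. Two components suffice for mEGFP-class
#' donors. If polarized (VV, VH) decay pairs are supplied, the
#' depolarization time and fundamental anisotropy are subsequently
#' refined by minimizing the Poisson deviance with the donor pattern
#' fixed.
#'
#' @param vm_decays List of VM [decay_histogram()] objects (weights from
#'   [compose_vm()] are used when present, else Poisson weights).
#' @param profiles An [instrument_profiles()] shared by all decays.
#' @param n_components Number of donor lifetimes (default 2).
#' @param start_tau Starting lifetimes in ns.
#' @param polarized_pairs Optional list of `list(vv =, vh =)` histogram
#'   pairs for the anisotropy refinement.
#' @param r0_start Start value of the fundamental anisotropy.
#' @param rho_start Start depolarization time in ns.
#' @return A list with `donor` ([donor_pattern()]), `chi2_r` (joint
#'   reduced chi-square), `aniso` (an [anisotropy_pattern()], when
#'   polarized pairs were given), and `convergence` (0 = success).
#' @export
fit_donor_pattern <- function(vm_decays, profiles, n_components = 2,
                              start_tau = seq(1, 3.5,
                                              length.out = n_components),
                              polarized_pairs = NULL,
                              r0_start = 0.37, rho_start = 45) {
  stopifnot(length(vm_decays) >= 2, inherits(profiles, "instrument_profiles"))
  nd <- n_components
  counts <- lapply(vm_decays, function(d) d$counts)
  weights <- lapply(vm_decays, function(d)
    if (is.null(d$weights)) d$counts else d$weights)

  obj <- function(theta) {
    tau <- exp(theta[seq_len(nd)])
    fr <- if (nd > 1) .softmax(theta[nd + seq_len(nd - 1)]) else 1
    don <- donor_pattern(tau, fr)
    shape <- model_donor(don, nuisance_params(a0 = 1), profiles)
    tot <- 0
    for (d in seq_along(counts)) {
      a0 <- .ls_amplitude(counts[[d]], shape, weights[[d]])
      keep <- weights[[d]] > 0
      tot <- tot + sum((counts[[d]][keep] - a0 * shape[keep])^2 /
                         weights[[d]][keep])
    }
    tot
  }
  theta0 <- c(log(start_tau), rep(0, nd - 1))
  fit <- optim(theta0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  tau <- exp(fit$par[seq_len(nd)])
  fr <- if (nd > 1) .softmax(fit$par[nd + seq_len(nd - 1)]) else 1
  if (nd > 1 && any(diff(sort(tau)) < 0.05))
    warning("degenerate donor fit: lifetimes nearly coincide")
  donor <- donor_pattern(tau, fr)
  n_eff <- sum(vapply(weights, function(w) sum(w > 0), 0))
  n_par <- (2 * nd - 1) + length(counts)
  out <- list(donor = donor,
              chi2_r = fit$value / (n_eff - n_par),
              convergence = fit$convergence)

  if (!is.null(polarized_pairs)) {
    fret0 <- fret_pattern(k = 1, a = 1, x_fret = 0)
    aobj <- function(th) {
      an <- anisotropy_pattern(r0 = plogis(th[1]) * 0.4, rho = exp(th[2]),
                               G = profiles$G)
      dev <- 0
      for (pp in polarized_pairs) {
        mvv <- model_polarized(donor, fret0, an, nuisance_params(1),
                               profiles, "VV")
        mvh <- model_polarized(donor, fret0, an, nuisance_params(1),
                               profiles, "VH")
        nd_ <- sum(pp$vv$counts) + sum(pp$vh$counts)
        sc <- nd_ / (sum(mvv) + sum(mvh))
        dev <- dev + chi2_ml(pp$vv, sc * mvv) + chi2_ml(pp$vh, sc * mvh)
      }
      dev
    }
    afit <- optim(c(qlogis(r0_start / 0.4), log(rho_start)), aobj,
                  method = "Nelder-Mead",
                  control = list(maxit = 500, reltol = 1e-9))
    out$aniso <- anisotropy_pattern(r0 = plogis(afit$par[1]) * 0.4,
                                    rho = exp(afit$par[2]), G = profiles$G)
    out$aniso_chi2_ml <- afit$value
  }
  out
}

#' Single-cell pattern fit of the FRET-quenched donor fraction
#'
#' Fits one whole-cell integrated polarized decay pair with the frozen
#' pattern library, freeing only `x_fret`, a single depolarization time
#' and the overall amplitude (solved analytically by total-count
#' matching, the Poisson maximum-likelihood solution for a free scale).
#' The objective is the Poisson deviance over both channels; bounded
#' optimization is started from several `x_fret` values to avoid local
#' minima.
#'
#' @param vv,vh Polarized [decay_histogram()] objects of one cell.
#' @param library A [pattern_library()].
#' @param profiles An [instrument_profiles()].
#' @param min_photons Minimum summed counts across both channels; decays
#'   below this are rejected (default 1e5).
#' @param starts Start values for `x_fret` (default 0.05 and 0.2).
#' @return An `xfret_fit` list: `x_fret`, `x_se` (from the observed
#'   information), `rho` (fitted depolarization time, ns), `chi2_ml`,
#'   `chi2_r_ls`, `n_par`, `total_photons`, `convergence`.
#' @export
fit_xfret <- function(vv, vh, library, profiles,
                      min_photons = 1e5, starts = c(0.05, 0.2)) {
  stopifnot(inherits(library, "pattern_library"),
            inherits(profiles, "instrument_profiles"))
  total <- sum(vv$counts) + sum(vh$counts)
  if (total < min_photons)
    stop(sprintf("photon-starved decay pair: %d < %d counts",
                 round(total), round(min_photons)))
  don <- library$donor
  kf <- library$fret_rates
  r0 <- library$aniso$r0
  G <- library$aniso$G

  models_at <- function(x, rho) {
    fr <- fret_pattern(kf$k, kf$a, x_fret = x)
    an <- anisotropy_pattern(r0 = r0, rho = rho, G = G)
    mvv <- model_polarized(don, fr, an, nuisance_params(1), profiles, "VV")
    mvh <- model_polarized(don, fr, an, nuisance_params(1), profiles, "VH")
    sc <- total / (sum(mvv) + sum(mvh))
    list(vv = sc * mvv, vh = sc * mvh)
  }
  obj <- function(par) {
    m <- models_at(par[1], exp(par[2]))
    chi2_ml(vv, m$vv) + chi2_ml(vh, m$vh)
  }
  lower <- c(0, log(1)); upper <- c(1, log(1000))
  best <- NULL
  for (x0 in starts) {
    f <- optim(c(x0, log(library$aniso$rho[1])), obj, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || f$value < best$value) best <- f
  }
  x_se <- NA_real_
  h <- try(stats::optimHess(best$par, obj), silent = TRUE)
  if (!inherits(h, "try-error")) {
    cv <- try(solve(h / 2), silent = TRUE)
    if (!inherits(cv, "try-error") && cv[1, 1] > 0)
      x_se <- sqrt(cv[1, 1])
  }
  m <- models_at(best$par[1], exp(best$par[2]))
  n_par <- 3L  # x_fret, rho, amplitude
  structure(
    list(x_fret = best$par[1], x_se = x_se, rho = exp(best$par[2]),
         chi2_ml = best$value,
         chi2_r_ls = chi2_ls(c(vv$counts, vh$counts), c(m$vv, m$vh), n_par),
         n_par = n_par, total_photons = total,
         convergence = best$convergence),
    class = "xfret_fit")
}

#' @export
print.xfret_fit <- function(x, ...) {
  cat(sprintf("<xfret_fit> x_FRET = %.4f +/- %.4f, rho = %.1f ns, chi2_ML = %.1f\n",
              x$x_fret, x$x_se, x$rho, x$chi2_ml))
  invisible(x)
}

# ---- conversion to oligomer fraction ---------------------------------------

#' Theoretical maximum x_FRET of a pure dimer sample
#'
#' For a fully dimeric sample the measurable FRET fraction is limited by
#' the fluorophore-cloud correction (the fraction of donor-acceptor
#' linker configurations within FRET range) and by the probability that a
#' dimer carrying an observable donor also carries a FRET-capable
#' acceptor: `x_fret_max = xi * p_ad`. Donor maturation cancels because
#' immature donors are invisible; acceptor maturation is taken as 1 since
#' even immature acceptors absorb.
#'
#' @param xi Cloud correction factor in (0, 1\] (default 0.465).
#' @param p_ad Donor-acceptor pairing probability in (0, 1\].
#' @return The maximum FRET-quenched fraction for a 100% dimer sample.
#' @examples
#' xfret_max_theoretical(0.465, 0.71)  # ~0.33 (monomer-control constructs)
#' xfret_max_theoretical(0.465, 0.78)  # ~0.36
#' @export
xfret_max_theoretical <- function(xi = 0.465, p_ad) {
  stopifnot(xi > 0, xi <= 1, p_ad > 0, p_ad <= 1)
  xi * p_ad
}

#' Convert a measured x_FRET into an oligomer fraction
#'
#' Linear rescaling by the sample-specific maximum: a cell whose donors
#' show `x_fret` quenching against a pure-dimer ceiling `x_fret_max`
#' carries `x_fret / x_fret_max` of its receptors in oligomers. Values
#' above 1 (possible through noise) are clipped with a warning.
#'
#' @param x_fret Measured FRET-quenched fraction(s), `>= 0`.
#' @param x_fret_max Maximum x_FRET of a pure dimer, `> 0`. Use the
#'   experimentally determined value when available, else
#'   [xfret_max_theoretical()].
#' @return Oligomer fraction(s) in \[0, 1\].
#' @examples
#' oligomer_fraction(0.01, 0.36)  # 1% x_FRET -> ~2.8% oligomers
#' @export
oligomer_fraction <- function(x_fret, x_fret_max) {
  if (any(x_fret_max <= 0)) stop("x_fret_max must be positive")
  if (any(x_fret < 0)) stop("x_fret must be non-negative")
  f <- x_fret / x_fret_max
  if (any(f > 1)) {
    warning("oligomer fraction above 1 clipped")
    f <- pmin(f, 1)
  }
  f
}

#' Receptor surface density from the mean pixel count rate
#'
#' Converts a fluorescence count rate into receptors per square
#' micrometer using the FCS-calibrated molecular brightness, correcting
#' for fluorophore maturation and for the fraction of molecules actually
#' residing in the membrane:
#' `density = rate / (brightness * power * maturation) * membrane_fraction
#' / pixel_area`.
#'
#' @param rate_hz Mean count rate per pixel in Hz, `>= 0`.
#' @param power_uw Excitation power in microwatts.
#' @param brightness Molecular brightness in Hz per molecule per
#'   microwatt (mEGFP 814, mCherry 264 on the reference setup).
#' @param maturation Fluorophore maturation efficiency (0.8 for mEGFP;
#'   use 1 for mCherry).
#' @param membrane_fraction Fraction of molecules in the membrane
#'   (default 0.6).
#' @param pixel_area_um2 Pixel area in square micrometers.
#' @return Receptor density per square micrometer.
#' @export
surface_density <- function(rate_hz, power_uw, brightness, maturation = 0.8,
                            membrane_fraction = 0.6, pixel_area_um2) {
  stopifnot(all(rate_hz >= 0), power_uw > 0, brightness > 0,
            maturation > 0, membrane_fraction > 0, membrane_fraction <= 1,
            pixel_area_um2 > 0)
  rate_hz / (brightness * power_uw * maturation) *
    membrane_fraction / pixel_area_um2
}

#' Oligomerization rate of a single cell
#'
#' Least-squares slope of the oligomer fraction over time, restricted to
#' the trailing time window (by default the last 3 hours, e.g. before an
#' apoptosis event). Negative rates are allowed: falling oligomer
#' fractions are a real observation.
#'
#' @param time_h Time points in hours.
#' @param fraction Oligomer fractions at those times.
#' @param window_h Width of the trailing window in hours (default 3).
#' @return The rate in percent per hour.
#' @export
oligomerization_rate <- function(time_h, fraction, window_h = 3) {
  stopifnot(length(time_h) == length(fraction))
  keep <- time_h >= max(time_h) - window_h
  if (sum(keep) < 2)
    stop("need at least two time points within the window")
  100 * unname(coef(lm(fraction[keep] ~ time_h[keep]))[2])
}

#' Assemble per-cell results with the proximity-FRET guard
#'
#' Builds the tidy per-cell result table and flags cells whose receptor
#' surface density exceeds the proximity-FRET onset; flagged cells must
#' be excluded from oligomer statistics because random close packing
#' mimics binding at such densities.
#'
#' @param cell Cell identifiers.
#' @param x_fret Fitted FRET-quenched fractions.
#' @param density Receptor surface densities per square micrometer.
#' @param x_fret_max Conversion ceiling (scalar).
#' @param x_se,time_h,fate Optional per-cell columns.
#' @param proximity_threshold Density above which cells are flagged
#'   (default 1000 per square micrometer).
#' @return A data.frame with columns `cell`, `x_fret`, `x_se`, `density`,
#'   `oligomer_fraction`, `time_h`, `fate`, `proximity_flagged`.
#' @export
cell_records <- function(cell, x_fret, density, x_fret_max,
                         x_se = NA_real_, time_h = NA_real_,
                         fate = NA_character_,
                         proximity_threshold = 1000) {
  flagged <- density > proximity_threshold
  data.frame(cell = cell, x_fret = x_fret, x_se = x_se, density = density,
             oligomer_fraction = oligomer_fraction(x_fret, x_fret_max),
             time_h = time_h, fate = fate,
             proximity_flagged = flagged, stringsAsFactors = FALSE)
}
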