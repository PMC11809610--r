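# ---- calibrated constants --------------------------------------------------

#' Calibrated reference constants
#'
#' The frozen calibration registry used throughout the package: the
#' two-component donor decay pattern, the two-rate FRET pattern, the
#' fundamental anisotropy and typical depolarization time of a flexibly
#' tethered fluorescent protein, the polarization detection-efficiency
#' ratio G, the fluorophore-cloud correction factor, donor-acceptor
#' pairing probabilities for the monomer/dimer reference constructs, the
#' mEGFP maturation efficiency, molecular brightness values for the
#' mEGFP and mCherry channels, and the surface-density threshold above
#' which proximity FRET sets in. Each entry carries a short note on its
#' origin.
#'
#' @return A named list of constants. `donor` and `fret` are ready-made
#'   [donor_pattern()] / rate-amplitude lists; scalars are plain numbers.
#' @examples
#' k <- oq_constants()
#' k$xi * k$p_ad["CD95"]   # theoretical maximum x_FRET for a pure dimer
#' @export
oq_constants <- function() {
  list(
    donor = donor_pattern(tau = c(1.68, 2.75), fractions = c(0.5, 0.5)),
    fret_rates = list(k = c(0.154, 1.346), a = c(0.75, 0.25)),
    r0 = 0.37,
    rho_ns = 45,
    G = 1.087,
    xi = 0.465,
    p_ad = c(CD95 = 0.71, CTLA4 = 0.78),
    eta_megfp = 0.80,
    brightness_hz_per_molecule_uw = c(mEGFP = 814, mCherry = 264),
    membrane_fraction = 0.60,
    proximity_threshold_per_um2 = 1000,
    notes = c(
      donor = "joint two-component donor-only calibration fit",
      fret_rates = "two-rate FRET pattern from the dimer-control calibration",
      r0 = "fundamental anisotropy start value of the pattern fit",
      rho_ns = "typical depolarization time of a tethered fluorescent protein",
      G = "polarized detection-efficiency ratio of the instrument",
      xi = "fluorophore-cloud correction from accessible-volume modeling",
      p_ad = "probability of a FRET-capable donor-acceptor pair per construct",
      eta_megfp = "mEGFP maturation efficiency",
      brightness_hz_per_molecule_uw = "FCS molecular brightness per channel",
      membrane_fraction = "receptor fraction localized to the membrane",
      proximity_threshold_per_um2 = "onset density of proximity FRET"))
}

#' Default pattern library from the calibration registry
#'
#' Convenience wrapper bundling the calibrated donor pattern, FRET rates
#' and anisotropy parameters into a [pattern_library()].
#'
#' @return A `pattern_library` object.
#' @export
default_pattern_library <- function() {
  k <- oq_constants()
  pattern_library(
    donor = k$donor,
    fret_rates = k$fret_rates,
    aniso = anisotropy_pattern(r0 = k$r0, rho = k$rho_ns, G = k$G))
}

# ---- synthetic instrument --------------------------------------------------

#' Synthetic instrument profiles (Gaussian IRF)
#'
#' Generates an idealized instrument for simulations: a Gaussian IRF of
#' given width centered at `t0` (identical in both polarized channels
#' unless widths are given per channel), no autofluorescence by default.
#' This emulates the measured unit-integral IRF of a real setup; it does
#' not reproduce detector afterpulsing or IRF tails.
#'
#' @param n_bins Number of time bins (default 512).
#' @param period Repetition period in ns (default 32, i.e. ~31 MHz).
#' @param irf_sigma Gaussian IRF standard deviation in ns (default 0.15,
#'   a ~350 ps FWHM typical of hybrid detectors).
#' @param t0 IRF center in ns (default 2).
#' @param G Detection-efficiency ratio stored with the profiles.
#' @return An [instrument_profiles()] object.
#' @export
synthetic_instrument <- function(n_bins = 512, period = 32,
                                 irf_sigma = 0.15, t0 = 2, G = 1) {
  grid <- decay_grid(n_bins, period)
  irf <- exp(-0.5 * ((grid$times - t0) / irf_sigma)^2)
  instrument_profiles(grid, irf_vv = irf, irf_vh = irf, G = G)
}

# ---- photon sampling -------------------------------------------------------

#' Sample polarized TCSPC photon histograms from a decay model
#'
#' Computes the polarized forward-model curves for both channels and
#' draws a multinomial sample of `photons` photon arrival times over the
#' joint (VV, VH) bin space, so that expected counts equal the model
#' curve scaled to the requested total. Reproducible under `seed`.
#'
#' @param donor A [donor_pattern()].
#' @param fret A [fret_pattern()] (`x_fret = 0` simulates donor-only data).
#' @param aniso An [anisotropy_pattern()].
#' @param profiles An [instrument_profiles()].
#' @param photons Total number of photons across both channels.
#' @param nuisance A [nuisance_params()]; the amplitude only shapes the
#'   relative curve, totals are set by `photons`.
#' @param seed Optional integer seed.
#' @return A list with `vv` and `vh` [decay_histogram()] objects.
#' @export
generate_tcspc_photons <- function(donor, fret, aniso, profiles, photons,
                                   nuisance = nuisance_params(), seed = NULL) {
  stopifnot(photons >= 0)
  if (!is.null(seed)) set.seed(seed)
  mvv <- model_polarized(donor, fret, aniso, nuisance, profiles, "VV")
  mvh <- model_polarized(donor, fret, aniso, nuisance, profiles, "VH")
  p <- c(mvv, mvh)
  if (any(p < 0)) stop("model curve has negative values")
  n <- profiles$grid$n
  if (photons == 0) {
    counts <- numeric(2 * n)
  } else {
    counts <- as.numeric(rmultinom(1, size = photons, prob = p / sum(p)))
  }
  list(vv = decay_histogram(counts[seq_len(n)], profiles$grid, "VV"),
       vh = decay_histogram(counts[n + seq_len(n)], profiles$grid, "VH"))
}
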