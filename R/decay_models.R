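# ---- time grid -------------------------------------------------------------

#' Uniform TCSPC time grid
#'
#' Defines the uniform bin grid on which decays, instrument response
#' functions (IRF) and autofluorescence (AF) profiles live. Continuous decay
#' models are evaluated at bin centers; no intra-bin integration is
#' performed, which is accurate at instrument bin widths (tens of ps).
#'
#' @param n_bins Number of time bins.
#' @param period Laser repetition period T in ns. The grid spans one period.
#' @return An object of class `decay_grid` with elements `times` (bin-center
#'   times in ns), `dt` (bin width, ns), `period` and `n`.
#' @examples
#' g <- decay_grid(256, 32)
#' head(g$times)
#' @export
decay_grid <- function(n_bins, period) {
  stopifnot(n_bins >= 2, period > 0)
  dt <- period / n_bins
  structure(
    list(times = (seq_len(n_bins) - 0.5) * dt, dt = dt,
         period = period, n = as.integer(n_bins)),
    class = "decay_grid")
}

#' Binned photon-count decay histogram
#'
#' Container for one polarization channel of a TCSPC measurement: photon
#' counts per bin on a [decay_grid()], the detection channel, and optional
#' per-bin variance weights (used for composed VM signals, where Poisson
#' weights no longer equal the counts).
#'
#' @param counts Non-negative counts per bin (numeric for composed signals).
#' @param grid A [decay_grid()].
#' @param channel One of `"VV"`, `"VH"`, `"VM"`.
#' @param weights Optional per-bin variance weights; defaults to `NULL`,
#'   meaning Poisson weights (the counts themselves) apply.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(counts, grid, channel = c("VM", "VV", "VH"),
                            weights = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(grid, "decay_grid"))
  if (length(counts) != grid$n)
    stop("counts length does not match the grid")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(weights) && length(weights) != grid$n)
    stop("weights length does not match the grid")
  structure(
    list(counts = as.numeric(counts), grid = grid, channel = channel,
         weights = weights),
    class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> channel %s, %d bins over %.3g ns, %.4g counts\n",
              x$channel, x$grid$n, x$grid$period, sum(x$counts)))
  invisible(x)
}

# ---- patterns --------------------------------------------------------------

#' Donor-only decay pattern
#'
#' Multi-exponential description of the unquenched donor: lifetimes
#' `tau` (ns) and species fractions `fractions` summing to one. The decay
#' rate of component i is `1/tau[i]`.
#'
#' @param tau Lifetimes in ns, all positive.
#' @param fractions Species fractions, same length as `tau`, summing to 1.
#' @return A `donor_pattern` object with components sorted by ascending
#'   lifetime.
#' @export
donor_pattern <- function(tau, fractions) {
  stopifnot(length(tau) == length(fractions), all(tau > 0),
            all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("donor fractions must sum to 1")
  o <- order(tau)
  structure(list(tau = as.numeric(tau[o]),
                 fractions = as.numeric(fractions[o])),
            class = "donor_pattern")
}

#' FRET rate pattern
#'
#' FRET rate constants `k` (1/ns) with normalized amplitudes `a`
#' (summing to 1) and the FRET-active donor fraction `x_fret`. The
#' species fractions are `p_j = x_fret * a_j` for the quenched states and
#' `p_0 = 1 - x_fret` for the unquenched state.
#'
#' @param k FRET rate constants in 1/ns, all positive.
#' @param a Amplitudes of the FRET states, summing to 1.
#' @param x_fret Fraction of donors quenched by FRET, in \[0, 1\].
#' @return A `fret_pattern` object.
#' @export
fret_pattern <- function(k, a, x_fret) {
  stopifnot(length(k) == length(a), all(k > 0), all(a >= 0))
  if (abs(sum(a) - 1) > 1e-8) stop("FRET amplitudes must sum to 1")
  if (x_fret < 0 || x_fret > 1) stop("x_fret must lie in [0, 1]")
  structure(list(k = as.numeric(k), a = as.numeric(a),
                 x_fret = as.numeric(x_fret)),
            class = "fret_pattern")
}

#' Anisotropy (depolarization) pattern
#'
#' Fundamental anisotropy `r0`, depolarization correlation times `rho`
#' (ns) with fractions `p`, the polarization detection-efficiency ratio
#' `G`, and lens-mixing factors `l1`, `l2` (zero for a well-corrected
#' detection path; nonzero values use the standard detection-mixing form
#' but are untested against calibration data). The fixed polarization
#' prefactors are P_VV = +2 and P_VH = -1.
#'
#' @param r0 Fundamental anisotropy in \[0, 0.4\].
#' @param rho Depolarization times in ns.
#' @param p Fractions of the depolarization components, summing to 1.
#' @param G Detection-efficiency ratio between the polarized channels.
#' @param l1,l2 Lens depolarization mixing factors (default 0).
#' @return An `anisotropy_pattern` object.
#' @export
anisotropy_pattern <- function(r0, rho, p = rep(1 / length(rho), length(rho)),
                               G = 1, l1 = 0, l2 = 0) {
  stopifnot(r0 >= 0, r0 <= 0.4, all(rho > 0), length(rho) == length(p),
            G > 0)
  if (abs(sum(p) - 1) > 1e-8) stop("anisotropy fractions must sum to 1")
  structure(list(r0 = r0, rho = as.numeric(rho), p = as.numeric(p),
                 G = G, l1 = l1, l2 = l2),
            class = "anisotropy_pattern")
}

#' Nuisance amplitudes of a decay model
#'
#' Scaling and additive terms of the measured signal: decay amplitude
#' `a0`, autofluorescence amplitude `a_af`, scattered-light amplitude
#' `a_sc` (enters the parallel channel only), and a constant background
#' `bg` in counts per bin.
#'
#' @param a0 Decay amplitude (photon-count scale), `>= 0`.
#' @param a_af Autofluorescence amplitude, `>= 0`.
#' @param a_sc Scatter amplitude, `>= 0`.
#' @param bg Constant background counts per bin, `>= 0`.
#' @return A `nuisance_params` object.
#' @export
nuisance_params <- function(a0 = 1, a_af = 0, a_sc = 0, bg = 0) {
  stopifnot(a0 >= 0, a_af >= 0, a_sc >= 0, bg >= 0)
  structure(list(a0 = a0, a_af = a_af, a_sc = a_sc, bg = bg),
            class = "nuisance_params")
}

# ---- instrument profiles ---------------------------------------------------

.normalize_profile <- function(x, n, what) {
  if (is.null(x)) return(NULL)
  if (length(x) != n) stop(what, " length does not match the grid")
  if (any(x < 0)) stop(what, " must be non-negative")
  s <- sum(x)
  if (s <= 0) stop(what, " must have positive integral")
  x / s
}

#' Measured instrument profiles for both polarized channels
#'
#' Bundles the per-channel instrument response functions (normalized to
#' unit integral), optional autofluorescence profiles (also normalized;
#' their scale is carried by the nuisance amplitude), and sub-bin time
#' shifts. The VM-channel profiles are composed from the polarized ones
#' as `VV + 2 G VH` and renormalized, mirroring how composite
#' magic-angle-equivalent signals are built from the measured channels.
#'
#' @param grid A [decay_grid()].
#' @param irf_vv,irf_vh Per-bin IRF amplitudes for the two channels.
#' @param af_vv,af_vh Optional autofluorescence profiles.
#' @param t_sh_vv,t_sh_vh IRF time shifts in ns (sub-bin values allowed).
#' @param G Detection-efficiency ratio used for the VM composition.
#' @return An `instrument_profiles` object with one entry per channel,
#'   each holding `irf`, `af` and `t_sh`.
#' @export
instrument_profiles <- function(grid, irf_vv, irf_vh = irf_vv,
                                af_vv = NULL, af_vh = af_vv,
                                t_sh_vv = 0, t_sh_vh = 0, G = 1) {
  stopifnot(inherits(grid, "decay_grid"))
  irf_vv <- .normalize_profile(irf_vv, grid$n, "irf_vv")
  irf_vh <- .normalize_profile(irf_vh, grid$n, "irf_vh")
  af_vv <- .normalize_profile(af_vv, grid$n, "af_vv")
  af_vh <- .normalize_profile(af_vh, grid$n, "af_vh")
  irf_vm <- .normalize_profile(irf_vv + 2 * G * irf_vh, grid$n, "irf_vm")
  af_vm <- if (!is.null(af_vv))
    .normalize_profile(af_vv + 2 * G * af_vh, grid$n, "af_vm")
  structure(
    list(grid = grid,
         VV = list(irf = irf_vv, af = af_vv, t_sh = t_sh_vv),
         VH = list(irf = irf_vh, af = af_vh, t_sh = t_sh_vh),
         VM = list(irf = irf_vm, af = af_vm, t_sh = t_sh_vv),
         G = G),
    class = "instrument_profiles")
}

# ---- convolution -----------------------------------------------------------

#' Circular convolution with a (shifted) instrument response
#'
#' Convolves an ideal per-bin signal with the IRF over one repetition
#' period, wrapping contributions that extend past the period back to the
#' start. Implemented by multiplication in frequency space; the time shift
#' is applied there as a phase factor, so sub-bin shifts are supported.
#' For an IRF normalized to unit sum the total signal is preserved.
#'
#' @param ideal Per-bin ideal signal values.
#' @param irf Per-bin IRF values, same length.
#' @param shift Time shift of the IRF in ns (default 0).
#' @param period Repetition period T in ns; required when `shift != 0`.
#' @return Per-bin convolved values.
#' @export
circular_convolve <- function(ideal, irf, shift = 0, period = NULL) {
  n <- length(ideal)
  if (length(irf) != n) stop("ideal and irf must have the same length")
  fi <- stats::fft(ideal)
  fk <- stats::fft(irf)
  if (shift != 0) {
    if (is.null(period)) stop("period is required for a nonzero shift")
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    fk <- fk * exp(-2i * pi * k * shift / period)
  }
  Re(stats::fft(fi * fk, inverse = TRUE)) / n
}

.shifted_irf <- function(irf, shift, period) {
  if (shift == 0) return(irf)
  n <- length(irf)
  delta <- numeric(n); delta[1] <- 1
  circular_convolve(delta, irf, shift = shift, period = period)
}

# ---- ideal decays ----------------------------------------------------------

#' Ideal donor-only decay evaluated on a time grid
#'
#' \eqn{f^{DO}(t) = \sum_i p_i e^{-t/\tau_i}}, evaluated at bin centers
#' over a single period (no wraparound correction; the periodic overlap is
#' handled by the circular convolution with the IRF).
#'
#' @param times Bin-center times in ns.
#' @param donor A [donor_pattern()].
#' @return Per-bin ideal decay values (unit amplitude at t = 0).
#' @export
ideal_donor_decay <- function(times, donor) {
  stopifnot(inherits(donor, "donor_pattern"))
  drop(exp(-outer(times, 1 / donor$tau)) %*% donor$fractions)
}

#' FRET-induced donor quenching factor
#'
#' \eqn{\epsilon_D(t) = (1 - x) + x \sum_j a_j e^{-k_j t}}: the factor by
#' which FRET accelerates the donor decay in a mixture where only the
#' fraction x of donors is quenched. The homogeneous approximation (all
#' FRET species share the donor rates) makes the donor-acceptor decay a
#' simple product \eqn{f^{DA}(t) = f^{DO}(t)\,\epsilon_D(t)}.
#'
#' @param times Times in ns.
#' @param fret A [fret_pattern()].
#' @return Per-bin quenching factor values in (0, 1\].
#' @export
fret_quench_factor <- function(times, fret) {
  stopifnot(inherits(fret, "fret_pattern"))
  x <- fret$x_fret
  (1 - x) + x * drop(exp(-outer(times, fret$k)) %*% fret$a)
}

.ideal_da_decay <- function(times, donor, fret) {
  ideal_donor_decay(times, donor) * fret_quench_factor(times, fret)
}

.aniso_decay <- function(times, aniso) {
  aniso$r0 * drop(exp(-outer(times, 1 / aniso$rho)) %*% aniso$p)
}

# ---- forward models --------------------------------------------------------

.assemble_model <- function(ideal, nuisance, prof, grid, scatter = TRUE) {
  out <- nuisance$a0 *
    circular_convolve(ideal, prof$irf, prof$t_sh, grid$period)
  if (nuisance$a_af > 0) {
    if (is.null(prof$af)) stop("AF amplitude given but no AF profile")
    out <- out + nuisance$a_af *
      circular_convolve(prof$af, prof$irf, prof$t_sh, grid$period)
  }
  if (scatter && nuisance$a_sc > 0)
    out <- out + nuisance$a_sc * .shifted_irf(prof$irf, prof$t_sh, grid$period)
  out + nuisance$bg
}

#' Donor-only VM decay model
#'
#' Forward model of the total (magic-angle-equivalent) donor fluorescence
#' decay: the ideal multi-exponential donor decay circularly convolved
#' with the shifted VM IRF, plus autofluorescence (the measured AF profile
#' convolved with the IRF), scattered light (the shifted IRF itself) and a
#' constant background.
#'
#' @param donor A [donor_pattern()].
#' @param nuisance A [nuisance_params()].
#' @param profiles An [instrument_profiles()] on the model grid.
#' @return Per-bin model counts for the VM channel.
#' @export
model_donor <- function(donor, nuisance, profiles) {
  stopifnot(inherits(profiles, "instrument_profiles"))
  ideal <- ideal_donor_decay(profiles$grid$times, donor)
  .assemble_model(ideal, nuisance, profiles$VM, profiles$grid)
}

#' Donor-acceptor VM decay model (mixture with partial FRET quenching)
#'
#' As [model_donor()], with the ideal decay replaced by the
#' donor-acceptor decay of a mixture in which the fraction `x_fret` of
#' donors is quenched at the pattern's FRET rates. With `x_fret = 0` the
#' model reduces exactly to the donor-only model.
#'
#' @param donor A [donor_pattern()].
#' @param fret A [fret_pattern()] (carries `x_fret`).
#' @param nuisance A [nuisance_params()].
#' @param profiles An [instrument_profiles()].
#' @return Per-bin model counts for the VM channel.
#' @export
model_fret <- function(donor, fret, nuisance, profiles) {
  stopifnot(inherits(profiles, "instrument_profiles"))
  ideal <- .ideal_da_decay(profiles$grid$times, donor, fret)
  .assemble_model(ideal, nuisance, profiles$VM, profiles$grid)
}

#' Polarization-resolved decay model (VV or VH channel)
#'
#' Forward model for one polarized detection channel. The ideal polarized
#' decay is
#' \eqn{f_{pa}(t) = f^{DA}(t) + P_{pa}\, r_0 \sum_{i,j,l} p^{DA}_{ij} p^{AN}_l
#' e^{-(k^{DA}_{ij}+k^{AN}_l)t}} with fixed prefactors P_VV = +2 and
#' P_VH = -1. The VH channel is additionally scaled by 1/G (the relative
#' detection efficiency of the perpendicular channel), so that composing
#' the two channels as `VV + 2 G VH` cancels all depolarization terms and
#' recovers three times the VM decay. Scattered light enters the VV
#' channel only; each channel uses its own IRF, AF, shift and background.
#'
#' @param donor A [donor_pattern()].
#' @param fret A [fret_pattern()]; use `x_fret = 0` for donor-only data.
#' @param aniso An [anisotropy_pattern()].
#' @param nuisance A [nuisance_params()].
#' @param profiles An [instrument_profiles()].
#' @param channel `"VV"` or `"VH"`.
#' @return Per-bin model counts for the requested channel.
#' @export
model_polarized <- function(donor, fret, aniso, nuisance, profiles,
                            channel = c("VV", "VH")) {
  channel <- match.arg(channel)
  stopifnot(inherits(profiles, "instrument_profiles"),
            inherits(aniso, "anisotropy_pattern"))
  times <- profiles$grid$times
  fda <- .ideal_da_decay(times, donor, fret)
  # product form: sum over (i,j,l) factorizes into f_DA(t) * r(t)/r0 terms
  rterm <- .aniso_decay(times, aniso)
  p <- if (channel == "VV") 2 else -1
  ideal <- fda * (1 + p * rterm)
  if (aniso$l1 != 0 || aniso$l2 != 0) {
    # detection-lens mixing hook (standard mixing form); identity at 0
    ideal_vv <- fda * (1 + 2 * rterm)
    ideal_vh <- fda * (1 - rterm)
    ideal <- if (channel == "VV") ideal_vv + aniso$l1 * (ideal_vh - ideal_vv)
             else ideal_vh - aniso$l2 * (ideal_vh - ideal_vv)
  }
  if (channel == "VH") ideal <- ideal / aniso$G
  .assemble_model(ideal, nuisance, profiles[[channel]], profiles$grid,
                  scatter = (channel == "VV"))
}

# ---- VM composition --------------------------------------------------------

#' Compose a VM decay from polarized channels
#'
#' Builds the total-intensity (magic-angle-equivalent) signal
#' `VM = VV + 2 G VH` from the two measured polarized histograms, with
#' per-bin variance weights from uncertainty propagation,
#' `w = VV + 4 G^2 VH`.
#'
#' @param vv,vh [decay_histogram()] objects on the same grid.
#' @param G Detection-efficiency ratio.
#' @return A `decay_histogram` with channel `"VM"` and propagated weights.
#' @export
compose_vm <- function(vv, vh, G) {
  stopifnot(inherits(vv, "decay_histogram"), inherits(vh, "decay_histogram"))
  if (!isTRUE(all.equal(vv$grid$times, vh$grid$times)))
    stop("VV and VH histograms are on different grids")
  decay_histogram(vv$counts + 2 * G * vh$counts, vv$grid, channel = "VM",
                  weights = vv$counts + 4 * G^2 * vh$counts)
}

# ---- goodness of fit -------------------------------------------------------

#' Reduced least-squares chi-square
#'
#' \eqn{\chi^2_{r,LS} = \frac{1}{n - n_{par}}\sum_i (d_i - m_i)^2 / w_i}
#' with per-bin variance weights. For directly measured channels the
#' Poisson weights are the counts themselves; for composed VM signals use
#' the propagated weights from [compose_vm()]. Bins with zero weight are
#' excluded from the sum (and from the degrees of freedom), since Poisson
#' weighting by observed counts is undefined there.
#'
#' @param data A [decay_histogram()] or numeric vector of counts.
#' @param model Per-bin model counts.
#' @param n_par Number of fitted parameters.
#' @param weights Optional per-bin weights; defaults to the histogram's
#'   stored weights, else to the counts.
#' @return The reduced chi-square value.
#' @export
chi2_ls <- function(data, model, n_par, weights = NULL) {
  counts <- if (inherits(data, "decay_histogram")) data$counts else data
  if (is.null(weights) && inherits(data, "decay_histogram"))
    weights <- data$weights
  if (is.null(weights)) weights <- counts
  if (length(model) != length(counts)) stop("model/data length mismatch")
  keep <- weights > 0
  n_eff <- sum(keep)
  if (n_par >= n_eff) stop("n_par must be smaller than the number of bins")
  sum((counts[keep] - model[keep])^2 / weights[keep]) / (n_eff - n_par)
}

#' Poisson maximum-likelihood chi-square (deviance)
#'
#' \eqn{\chi^2_{ML} = 2[N_{mod} - N_{exp} + \sum_i d_i \ln(d_i/m_i)]},
#' the Poisson deviance between data and model. Zero-count bins contribute
#' only their model counts; it is an error for the model to be
#' non-positive where counts were observed. More reliable than the
#' least-squares estimator for low-count data (decay tails).
#'
#' @param data A [decay_histogram()] or numeric vector of counts.
#' @param model Per-bin model counts.
#' @return The deviance (non-negative; zero iff model equals data).
#' @export
chi2_ml <- function(data, model) {
  counts <- if (inherits(data, "decay_histogram")) data$counts else data
  if (length(model) != length(counts)) stop("model/data length mismatch")
  pos <- counts > 0
  if (any(model[pos] <= 0))
    stop("model must be positive wherever counts were observed")
  2 * (sum(model) - sum(counts) +
         sum(counts[pos] * log(counts[pos] / model[pos])))
}

#' Fit diagnostics container
#'
#' @param chi2_r_ls Reduced least-squares chi-square.
#' @param chi2_ml Poisson deviance.
#' @param n_par Number of fitted parameters.
#' @param residuals Per-bin residuals (data minus model).
#' @return A `fit_diagnostics` object.
#' @export
fit_diagnostics <- function(chi2_r_ls, chi2_ml, n_par, residuals = NULL) {
  stopifnot(chi2_ml >= -1e-9)
  structure(list(chi2_r_ls = chi2_r_ls, chi2_ml = chi2_ml,
                 n_par = as.integer(n_par), residuals = residuals),
            class = "fit_diagnostics")
}
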