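---
title: "Quantifying membrane-receptor oligomerization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-receptor oligomerization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoquant)
```

Death receptors such as CD95 (Fas) signal apoptosis after their trimeric
ligand binds, and whether the unliganded receptor is a monomer, dimer or
higher oligomer has direct mechanistic consequences. `oligoquant`
implements a set of complementary fluorescence readouts that together
quantify the oligomeric state of membrane receptors in cells: FRET-based
whole-cell lifetime analysis (CELFIS), confocal photobleaching step
analysis (cPBSA), STED-like spot brightness analysis, FCS, and
Hill-equation modeling of apoptosis dynamics. Every analysis has a
matched seeded generator, so the full pipeline runs and is validated at
desk scale.

## Polarization-resolved TCSPC decay models

Photon arrival times after pulsed excitation are histogrammed on a
uniform grid spanning one repetition period $T$ (default 512 bins over
32 ns). Continuous models are evaluated at bin centers; at instrument
bin widths the intra-bin integration error is negligible.

The unquenched donor decays multi-exponentially,
$f^{DO}(t) = \sum_i p_i^{DO} e^{-t/\tau_i^{DO}}$, with two components
sufficient for mEGFP-class donors. In a mixture where only a fraction
$x_{FRET}$ of donors is quenched by a nearby acceptor, the homogeneous
approximation factorizes the donor–acceptor decay as
$$f^{DA}(t) = f^{DO}(t)\,\Big[(1 - x_{FRET}) + x_{FRET}
\sum_j a_j^{FRET} e^{-k_j^{FRET} t}\Big],$$
so $x_{FRET}$ enters linearly — the key to a stable single-parameter
readout. Polarized detection adds rotational depolarization:
$$f_{pa}(t) = f^{DA}(t)\,\big[1 + P_{pa}\, r_0\, e^{-t/\rho}\big],
\qquad P_{VV} = +2,\; P_{VH} = -1,$$
with a single depolarization time $\rho$ (tens of ns for a flexibly
tethered fluorescent protein). Measured signals are the ideal decays
circularly convolved with the channel's unit-integral IRF (implemented
by FFT; sub-bin IRF time shifts are phase factors in frequency space),
plus an autofluorescence profile convolved with the IRF, scattered light
(the shifted IRF, parallel channel only) and a constant background.

**Detection-efficiency convention.** The perpendicular-channel model is
scaled by $1/G$, where $G$ is the polarization detection-efficiency
ratio (1.087 on the reference instrument). With this convention the
composite total-intensity signal $f_{VM} = f_{VV} + 2G\,f_{VH}$ cancels
all depolarization terms exactly and equals $3 f^{DA}$, which we verify
to $10^{-10}$ relative. (Stating the efficiency on the other side of
the composition would leave a residual $G^2$ anisotropy term; only this
convention is self-consistent.) VM bin variances follow uncertainty
propagation, $w_i = f_{VV}(t_i) + 4G^2 f_{VH}(t_i)$.

Two goodness-of-fit estimators are provided: a reduced least-squares
$\chi^2_{r,LS}$ with Poisson (or propagated) weights, and the Poisson
deviance $\chi^2_{ML} = 2[N_{mod} - N_{exp} + \sum_i d_i \ln(d_i/m_i)]$.
The deviance is used for final single-cell fits because it remains
unbiased in the low-count decay tail; zero-count bins contribute their
model counts only, and zero-weight bins are excluded from the
least-squares sum (Poisson weighting by observed counts is undefined
there).

## The pattern fit (CELFIS)

Calibration proceeds in stages mirroring the measurement workflow:
donor-only VM decays from many regions of interest are fitted jointly
(`fit_donor_pattern`) with shared lifetimes/fractions and analytic
per-decay amplitudes; polarized donor pairs then refine $r_0$ and
$\rho$ by deviance minimization. The resulting pattern —
lifetimes $\{1.68\,(0.5),\,2.75\,(0.5)\}$ ns, FRET rates
$\{0.154\,(0.75),\,1.346\,(0.25)\}$ ns$^{-1}$, $r_0 = 0.37$ — is frozen
in `default_pattern_library()`.

Single-cell fits (`fit_xfret`) integrate all membrane photons of a cell
into one polarized decay pair and free only $x_{FRET}$, one
depolarization time and the overall amplitude. The amplitude has a
closed-form Poisson-ML solution (total-count matching), leaving a
two-parameter bounded optimization (L-BFGS-B on
$x_{FRET} \in [0,1]$ and $\log \rho$), multi-started from
$x_{FRET} \in \{0.05, 0.2\}$ to avoid local minima. Decay pairs below a
configurable photon floor (default $10^5$ counts) are rejected; the
method's precision claim presumes high counts. Standard errors come
from the observed information at the optimum.

**Conversion to an oligomer fraction.** Not every true dimer shows
FRET: with long flexible linkers only the fraction $\xi$ of
donor–acceptor configurations lies within FRET range (cloud correction,
0.465 from accessible-volume modeling, consumed here as a constant),
and only the fraction $p_{AD}$ of dimers carrying an observable donor
also carries a FRET-capable acceptor (0.71 or 0.78 depending on the
construct pair; their combinatorial derivation is not re-implemented —
the values are inputs). Donor maturation cancels (immature donors are
invisible); acceptor maturation counts as 1 because immature acceptors
still absorb. Hence
$x_{FRET,max} = \xi\, p_{AD} \approx 33\%$ or $36\%$, and the oligomer
fraction is $x_{FRET}/x_{FRET,max}$, so 1% measured $x_{FRET}$
corresponds to ≈2.8% of receptors in oligomers. When an experimental
$x_{FRET,max}$ is available it takes precedence over the theoretical
product.

Receptor surface densities come from the mean pixel count rate via the
FCS-calibrated molecular brightness (814 / 264 Hz per molecule per µW
for the two channels), corrected for 80% donor maturation and the ~60%
membrane-localized fraction. Above ~1000 receptors/µm² random close
packing produces *proximity FRET* that mimics binding; `cell_records`
flags such cells and they must be excluded from oligomer statistics.
Per-cell oligomerization rates are trailing-window least-squares slopes
(default 3 h); negative rates are allowed.

## Photobleaching step analysis (cPBSA)

Spots are selected on a Gaussian-smoothed (σ = 1 px) overview image as
local maxima above 3–5 counts, discarding *both* members of any pair
closer than 450 nm so each trace records one assembly. Step counting
uses the Kalafut–Visscher change-point detector: greedy forward
addition of change points to a piecewise-constant fit, accepting a
split only while the Schwarz information criterion
$SIC = (k+2)\ln N + N \ln \hat\sigma^2$ decreases and only when the
level difference across the new boundary reaches the minimum step size.
That threshold is the detector's sole user input and scales linearly
with excitation power, $50\, p_{485} / 1.36\,\mu W$ counts per 5-ms bin
(10 kHz at 1.36 µW). On traces of ≤64 bins with up to two true steps
the greedy fit provably matches exhaustive SIC minimization in our
property tests. Downward transitions are bleaching steps; upward
transitions (blinking) are fitted but only flagged. The background is
the final segment mean — traces are long enough (3 s) to bleach fully.

`integrated_counts` sums photons from the trace start to the last
bleaching transition, background-subtracted. Regressing the per-class
mean integrated counts on the step number — by *orthogonal* (total
least squares) regression, each class weighted by its population —
yields the photon budget per fluorophore and should agree between
samples if steps are counted correctly.

**Crowding.** Incomplete maturation ($\eta \approx 0.8$ for mEGFP)
*lowers* the observed mean step number while co-localization of
independent molecules *raises* it. Conditioned on detection (at least
one visible fluorophore), an $n$-mer shows
$n\eta/(1-(1-\eta)^n)$ steps on average — 1 for a monomer, ≈1.667 for a
pseudo-dimer at $\eta = 0.8$. The crowding factor is the average of the
observed/expected ratios of the monomer and pseudo-dimer controls;
observed means of 1.33 and 1.92 give $k_{crowd} = 1.24$. The companion
quantity $f_{no\,crowd}$ needs a spot-occupancy model we do not have;
it is deliberately returned as `NA` rather than guessed.

The trace generator draws per-fluorophore visibility (Bernoulli
$\eta$), exponential bleach times discretized to bin boundaries
(negligible at 5-ms bins; it makes the no-noise limit an exact
staircase), and Poisson counts. It does not emulate blinking, detector
afterpulsing or focus drift — so KV validation on it demonstrates
change-point correctness, not robustness to those artifacts.

## STED-like spot images

The simulator follows the composite-image recipe: per object, $n$
coincident 2D Gaussians (sub-resolution oligomer; an offset-geometry
hook exists) with peak amplitudes drawn normally around $\langle Q
\rangle$ with $\sigma_{\langle Q \rangle} = 0.3\langle Q \rangle$ (the
brightness dispersion caused by random dipole orientations), Poisson
noise on the 25×25 px stamp, placement at uniform integer coordinates,
then per-pixel Poisson background; images save as unsigned 16-bit TIFF.
Defaults $\sigma_X = 2.5$ px and $\langle Q \rangle = 5$ are chosen so
monomer spot statistics (fitted σ of 2–2.5 px, order-1 mean photons per
pixel) resemble monomer-control measurements qualitatively; the
original tabulated simulation parameters are not available, so no
numerical match is claimed. Analysis thresholds the image at one
photon, keeps connected regions of ≥9 px, and refines each center by an
11×11 px elliptical-Gaussian least-squares fit on the *raw* image,
reporting $\sigma = \sqrt{\sigma_x \sigma_y}$, the amplitude and the
window-mean photons per pixel. No deconvolution is used on simulated
images (none is needed for detection at these densities), and none is
implemented for measured ones.

Spatial randomness of spot centers is assessed with the
pair-correlation function
$$g(r) = \frac{1}{\pi \rho^2 r\, \gamma(r)}
\sum_{i<j} k\big(r - \lVert p_i - p_j \rVert\big)$$
using an Epanechnikov kernel (bandwidth 5 nm, bins 10 nm) and the
isotropized set covariance $\gamma(r)$ of the rectangular window as
edge correction; $g \equiv 1$ for complete spatial randomness, which
the estimator reproduces within sampling error on uniform simulations.
Steady-state spot anisotropy is
$r = (I_P - G I_S)/(I_P + 2 G I_S)$.

## FCS

Correlation curves are fitted with two 3D-diffusion terms, a
cytoplasmic and a membrane species,
$$G(t_c) = 1 + \sum_{s} \rho_s \Big(1 + \tfrac{t_c}{t_s}\Big)^{-1}
\Big(1 + \tfrac{t_c}{\kappa^2 t_s}\Big)^{-1/2} + G_\infty,$$
deliberately without a triplet/bunching term: on noisy live-cell curves
the extra term destabilizes the fit without moving the diffusion times.
(A disabled-by-default hook exists.) Weights are $1/SE^2$ from chunked
acquisition; the curve simulator reproduces that scheme (mean of
`n_chunks` noisy curves, standard-error weights; per-point noise scales
with the correlation amplitude plus a small floor so tail points keep
finite weight). "Fitting the diffusion times globally" is implemented
as shared times across curves with free per-curve amplitudes — this is
how the fixed membrane diffusion time of 0.60 ms is derived, which
`fit_fcs(fix_membrane_time = 0.60)` then clamps in routine fits.
Calibration helpers convert between diffusion time and coefficient,
$D = \omega_0^2 / 4 t_{diff}$, anchored by Rhodamine 110
(430 µm²/s at 22.5 °C, 600 µm²/s at 37 °C).

## Apoptosis dynamics

Cumulative apoptotic fractions follow the Hill equation
$$P(t) = P_{max} - \frac{P_{max} - P_{min}}{1 + (t/t_{half})^n},$$
fitted by weighted least squares on the per-frame cumulative curve
(default 15-min frames) with binomial-variance weights using a
continuity-adjusted fraction so empty and saturated frames keep finite
weight. Parameters are transformed to enforce
$0 \le P_{min} \le P_{max} \le 1$, $t_{half}, n > 0$; a series without
events returns a flat fit with a warning rather than an error. Event
detection in images is out of scope — event-time lists are the input
boundary. The open question of per-timepoint least squares versus
per-cell likelihood is resolved in favor of per-timepoint least
squares, matching how replicate percentage curves are typically
reported; for the sample sizes involved (hundreds of cells) the two
give indistinguishable half-times in our recovery tests.

## Numerical and design choices

* Bounded $\chi^2_{ML}$ minimization (L-BFGS-B) with multi-start for
  $x_{FRET}$; the amplitude is profiled out analytically in both the
  ML (count matching) and LS (weighted projection) senses.
* Ideal decays are evaluated over a single period without a wraparound
  factor; the circular convolution supplies the periodic overlap. The
  single-period integral equals $\sum_i p_i \tau_i$ to $10^{-6}$ on
  fine grids.
* Degenerate donor fits (coinciding lifetimes) warn rather than fail;
  boundary parameters in the Hill fit get ridge-stabilized covariance.
* KV fits reject candidate splits below the minimum step size at
  proposal time and report `has_upward` when blinking-like transitions
  remain.
* Every randomized generator takes an explicit seed and is
  byte-reproducible.

## What the synthetic data do and do not show

The generators emulate Poisson photon statistics under the exact
forward models, ideal Gaussian IRFs, exponential bleaching, Gaussian
spot profiles and uniform spatial randomness. They do not emulate IRF
tails and afterpulsing, cell-to-cell pattern heterogeneity, blinking,
chromatic or drift artifacts, or receptor clustering. Consequently the
recovery tests demonstrate estimator correctness and precision under
the stated models — e.g. the $x_{FRET}$ recovery spread at $10^6$
photons (SD ≈ 0.004) is tighter than the ~1.6% precision quoted for
real cells, where pattern mismatch and biological scatter dominate —
not robustness to instrument artifacts.

Desk-scale problem sizes used by the test-suite and examples: 512-bin
decays, 20 calibration decays of $10^6$ photons, 100-replicate
single-cell recovery, STED images of 700–1200 px with 250–800 objects,
pair correlation on ≤1500 points. The full-scale defaults (2500 px,
10000 objects) remain the simulator defaults.

## Known limitations

* The cloud correction $\xi$ and pairing probabilities $p_{AD}$ are
  consumed as constants; changing linkers or label stoichiometry
  requires re-deriving them externally.
* $f_{no\,crowd}$ is not computed.
* No raw vendor TCSPC/TTTR parsing; delimited text and 16-bit TIFF are
  the exchange boundary.
* Pixel-wise FLIM maps, phasor analysis, acceptor-channel analysis and
  physical STED PSF modeling are out of scope.
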