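# oligoquant

Quantitative fluorescence toolbox for measuring the oligomeric state of
membrane receptors — built around the death receptor CD95 (Fas), whose
monomer/dimer/trimer equilibrium before and after ligand binding decides
how apoptosis is triggered. The package is for microscopists and
quantitative biologists who want the full analysis chain, validated on
synthetic data, without instrument-vendor software:

* **CELFIS** — whole-cell FRET lifetime analysis: polarization-resolved
  TCSPC decays are fitted with a frozen calibration pattern, freeing only
  the FRET-quenched donor fraction `x_FRET`, one depolarization time and
  the amplitude. The donor–acceptor decay of a partially quenched mixture
  factorizes as

  `f_DA(t) = f_DO(t) * [(1 − x_FRET) + x_FRET * Σ_j a_j exp(−k_j t)]`

  so `x_FRET` is a linear, stable readout. It converts to an oligomer
  fraction through the pure-dimer ceiling `x_FRET,max = ξ · p_AD`
  (fluorophore-cloud correction times donor–acceptor pairing
  probability): 1% `x_FRET` ≈ 2.8% of receptors in oligomers.
* **cPBSA** — confocal photobleaching step analysis: Kalafut–Visscher
  change-point step counting (Schwarz information criterion, minimum step
  size `50·p485/1.36 µW` counts per 5-ms bin as sole user input), photon
  budgets per fluorophore by weighted orthogonal regression, and a
  molecular crowding factor from monomer / pseudo-dimer controls.
* **STED spot analysis** — simulation of composite spot images (Gaussian
  spots with ±30% brightness dispersion, Poisson noise, 16-bit TIFF),
  threshold + connected-component detection with 2D-Gaussian refinement,
  and pair-correlation `g(r)` with kernel smoothing and edge correction.
* **FCS** — two-component (cytoplasm + membrane) diffusion model without
  a bunching term, chunk-based uncertainty weighting, optional fixed
  membrane diffusion time (0.60 ms), calibration via Rhodamine 110.
* **Apoptosis dynamics** — Hill-equation fits of cumulative apoptotic
  fractions, `P(t) = P_max − (P_max − P_min)/(1 + (t/t_half)^n)`.

Every analysis ships with a matched seeded generator (decay photon
sampling, bleach traces, composite images, correlation curves, event
times), so the whole pipeline is testable end to end at desk scale.

## Worked example

Simulate one cell's polarized decay pair at a known FRET fraction, fit
it with the calibrated pattern, and convert to an oligomer fraction:

```r
library(oligoquant)

lib  <- default_pattern_library()          # frozen calibration pattern
prof <- synthetic_instrument(G = lib$aniso$G)

sim <- generate_tcspc_photons(
  lib$donor,
  fret_pattern(lib$fret_rates$k, lib$fret_rates$a, x_fret = 0.12),
  lib$aniso, prof, photons = 1e6, seed = 7)

fit <- fit_xfret(sim$vv, sim$vh, lib, prof)
fit
#> <xfret_fit> x_FRET = 0.1168 +/- 0.0044, rho = 47.0 ns, chi2_ML = 956.1

xfret_max_theoretical(xi = 0.465, p_ad = 0.71)
#> [1] 0.33015
oligomer_fraction(fit$x_fret, 0.36)
#> [1] 0.3243921
```

The fitted `x_FRET` of 0.117 ± 0.004 recovers the simulated 0.12 within
its photon-limited error; against the experimental dimer ceiling of 36%
this cell would carry ~32% of its receptors in oligomers. A bleaching
trace of a pseudo-dimer and the crowding factor of the two controls:

```r
tr <- simulate_bleach_trace(2, brightness = 120, bleach_rate = 1.5,
                            background = 3, eta = 0.8, seed = 11)
kv_step_fit(tr)
#> <step_fit> 2 bleaching step(s), levels 222.5 > 123.2 > 3.2, N_Ph,int = 67363

crowding_metrics(1.33, 1.92, eta = 0.8)$k_crowd
#> [1] 1.241
```

(The acceptance script rounds this to the two decimals conventionally
reported, 1.24.)

Two fluorophores, two downward steps at ~120 counts/bin each; observed
control step means of 1.33 (monomer) and 1.92 (pseudo-dimer) at 80%
maturation give an average crowding factor of 1.24.

A thin command-line wrapper covers batch use
(`inst/cli/oligoquant <module> <verb> --help`), e.g.
`oligoquant synth decays`, `oligoquant celfis fit`,
`oligoquant sted simulate`, `oligoquant fcs fit`,
`oligoquant dynamics fit`.

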