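# Pattern-fit pipeline: donor calibration, single-cell x_FRET fits and
# the conversion to oligomer fractions and densities.

test_that("joint donor-pattern fit recovers the calibration lifetimes", {
  prof <- test_instrument(n_bins = 256)
  truth <- donor_pattern(c(1.68, 2.75), c(0.5, 0.5))
  set.seed(101)
  decays <- lapply(1:20, function(i) {
    m <- model_donor(truth, nuisance_params(1), prof)
    counts <- as.numeric(rmultinom(1, 1e6, m / sum(m)))
    decay_histogram(counts, prof$grid, "VM")
  })
  fit <- fit_donor_pattern(decays, prof, n_components = 2)
  expect_equal(fit$donor$tau, truth$tau, tolerance = 0.05 / 1.68)
  expect_lt(max(abs(fit$donor$fractions - truth$fractions)), 0.03)
  expect_equal(fit$chi2_r, 1, tolerance = 0.1)
})

test_that("two-component fit of single-exponential data degenerates cleanly", {
  prof <- test_instrument(n_bins = 256)
  truth <- donor_pattern(2.2, 1)
  set.seed(102)
  decays <- lapply(1:6, function(i) {
    m <- model_donor(truth, nuisance_params(1), prof)
    decay_histogram(as.numeric(rmultinom(1, 5e5, m / sum(m))),
                    prof$grid, "VM")
  })
  fit <- suppressWarnings(fit_donor_pattern(decays, prof, n_components = 2))
  collapsed <- min(fit$donor$fractions) < 0.05 ||
    diff(fit$donor$tau) < 0.15
  expect_true(collapsed)
})

test_that("polarized refinement recovers depolarization time and r0", {
  prof <- test_instrument(n_bins = 256)
  lib <- test_library()
  f0 <- fret_pattern(lib$fret_rates$k, lib$fret_rates$a, 0)
  set.seed(103)
  pairs <- lapply(1:3, function(i)
    generate_tcspc_photons(lib$donor, f0, lib$aniso, prof, 1e6))
  vm <- lapply(pairs, function(p) compose_vm(p$vv, p$vh, lib$aniso$G))
  fit <- fit_donor_pattern(vm, prof, n_components = 2,
                           polarized_pairs = pairs)
  expect_equal(fit$aniso$r0, 0.37, tolerance = 0.05)
  expect_equal(fit$aniso$rho, 45, tolerance = 0.25 * 45)
})

test_that("x_FRET pattern fit recovers null and positive fractions", {
  prof <- test_instrument()
  lib <- test_library()

  sim0 <- generate_tcspc_photons(
    lib$donor, fret_pattern(lib$fret_rates$k, lib$fret_rates$a, 0),
    lib$aniso, prof, 1e6, seed = 201)
  f0 <- fit_xfret(sim0$vv, sim0$vh, lib, prof)
  expect_lt(f0$x_fret, 0.01)

  xs <- vapply(1:5, function(i) {
    sim <- generate_tcspc_photons(
      lib$donor, fret_pattern(lib$fret_rates$k, lib$fret_rates$a, 0.15),
      lib$aniso, prof, 1e6, seed = 300 + i)
    fit_xfret(sim$vv, sim$vh, lib, prof)$x_fret
  }, 0)
  expect_equal(mean(xs), 0.15, tolerance = 0.02 / 0.15)

  sim_rho <- generate_tcspc_photons(
    lib$donor, fret_pattern(lib$fret_rates$k, lib$fret_rates$a, 0.15),
    lib$aniso, prof, 2e6, seed = 399)
  frho <- fit_xfret(sim_rho$vv, sim_rho$vh, lib, prof)
  expect_equal(frho$rho, 45, tolerance = 0.2 * 45)

  expect_error(fit_xfret(sim0$vv, sim0$vh, lib, prof, min_photons = 1e7),
               "photon-starved")
})

test_that("fitted x_FRET increases monotonically with the simulated value", {
  prof <- test_instrument()
  lib <- test_library()
  truth <- c(0, 0.1, 0.2, 0.3, 0.4)
  fitted <- vapply(seq_along(truth), function(i) {
    sim <- generate_tcspc_photons(
      lib$donor,
      fret_pattern(lib$fret_rates$k, lib$fret_rates$a, truth[i]),
      lib$aniso, prof, 5e5, seed = 400 + i)
    fit_xfret(sim$vv, sim$vh, lib, prof, min_photons = 1e5)$x_fret
  }, 0)
  expect_true(all(diff(fitted) > 0))
})

test_that("oligomer-fraction conversion constants behave as calibrated", {
  expect_equal(xfret_max_theoretical(0.465, 0.71), 0.330, tolerance = 1e-2)
  expect_equal(xfret_max_theoretical(0.465, 0.78), 0.363, tolerance = 1e-2)
  expect_equal(xfret_max_theoretical(1, 1), 1.0)
  expect_error(xfret_max_theoretical(0.465, 0))

  expect_equal(oligomer_fraction(0.01, 0.36), 0.01 / 0.36)
  expect_equal(oligomer_fraction(0, 0.36), 0)
  expect_equal(oligomer_fraction(0.36, 0.36), 1.0)
  expect_warning(f <- oligomer_fraction(0.5, 0.36), "clipped")
  expect_equal(f, 1.0)
  expect_error(oligomer_fraction(0.1, 0))
})

test_that("surface density converts count rates by brightness and maturation", {
  expect_equal(surface_density(0, 1, 814, 1, 1, 1), 0)
  expect_equal(surface_density(814, 1, 814, maturation = 1,
                               membrane_fraction = 1, pixel_area_um2 = 1),
               1)
  expect_equal(surface_density(814, 1, 814, maturation = 0.8,
                               membrane_fraction = 1, pixel_area_um2 = 1),
               1.25)
})

test_that("oligomerization rate is the windowed slope in percent per hour", {
  expect_equal(oligomerization_rate(c(0, 1, 2), c(0.1, 0.1, 0.1)), 0)
  expect_equal(oligomerization_rate(c(0, 1, 2), c(0, 0.06, 0.12)), 6)
  expect_equal(oligomerization_rate(c(0, 1, 2), c(0.12, 0.06, 0)), -6)
  # only the trailing window enters
  expect_equal(oligomerization_rate(c(0, 5, 6, 7), c(0.5, 0, 0.05, 0.1),
                                    window_h = 3), 5)
  expect_error(oligomerization_rate(1, 0.1), "two time points")
})

test_that("proximity-FRET guard flags high-density cells", {
  rec <- cell_records(cell = c("a", "b", "c"),
                      x_fret = c(0.02, 0.05, 0.3),
                      density = c(100, 900, 1500), x_fret_max = 0.36)
  expect_equal(rec$proximity_flagged, c(FALSE, FALSE, TRUE))
  expect_equal(rec$oligomer_fraction[1], 0.02 / 0.36)
  kept <- rec[!rec$proximity_flagged, ]
  expect_equal(nrow(kept), 2)
})
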