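# Forward decay models, VM composition and goodness-of-fit estimators.

delta_profiles <- function(n = 40, period = 32, G = 1) {
  grid <- decay_grid(n, period)
  irf <- numeric(n); irf[1] <- 1
  instrument_profiles(grid, irf_vv = irf, irf_vh = irf, G = G)
}

test_that("donor VM model reproduces pure and mixed exponentials", {
  prof <- delta_profiles(n = 40, period = 32)  # dt = 0.8, t = 2 is a center
  don <- donor_pattern(2, 1)
  m <- model_donor(don, nuisance_params(a0 = 1), prof)
  i2 <- which(abs(prof$grid$times - 2) < 1e-9)
  expect_length(i2, 1)
  expect_equal(m[i2], exp(-1), tolerance = 1e-12)

  don2 <- donor_pattern(c(1.68, 2.75), c(0.5, 0.5))
  expect_equal(ideal_donor_decay(1, don2),
               0.5 * exp(-1 / 1.68) + 0.5 * exp(-1 / 2.75),
               tolerance = 1e-12)
  expect_equal(ideal_donor_decay(1, don2), 0.6233, tolerance = 1e-4)

  bg_only <- model_donor(don2, nuisance_params(a0 = 0, bg = 7), prof)
  expect_equal(bg_only, rep(7, prof$grid$n))
  expect_true(all(model_donor(don2, nuisance_params(2, bg = 1), prof) >= 0))
})

test_that("FRET mixture model nests the donor model and is linear in x", {
  prof <- delta_profiles()
  don <- donor_pattern(c(1.68, 2.75), c(0.5, 0.5))
  kf <- list(k = c(0.154, 1.346), a = c(0.75, 0.25))
  nu <- nuisance_params(3)
  f0 <- fret_pattern(kf$k, kf$a, 0)
  expect_identical(model_fret(don, f0, nu, prof), model_donor(don, nu, prof))

  # full quenching of a single-exponential donor, direct evaluation
  don1 <- donor_pattern(2, 1)
  f1 <- fret_pattern(kf$k, kf$a, 1)
  ideal1 <- ideal_donor_decay(1, don1) * fret_quench_factor(1, f1)
  expect_equal(ideal1, 0.75 * exp(-0.654) + 0.25 * exp(-1.846),
               tolerance = 1e-12)
  expect_equal(ideal1, 0.4291, tolerance = 1e-3)

  fh <- fret_pattern(kf$k, kf$a, 0.5)
  mid <- model_fret(don, fh, nu, prof)
  avg <- (model_fret(don, f0, nu, prof) +
            model_fret(don, f1, nu, prof)) / 2
  expect_equal(mid, avg, tolerance = 1e-12)
  expect_error(fret_pattern(kf$k, kf$a, 1.2), "x_fret")
})

test_that("polarized models carry the anisotropy and compose back to VM", {
  prof <- delta_profiles(n = 512, period = 32)
  don <- donor_pattern(c(1.68, 2.75), c(0.5, 0.5))
  fr <- fret_pattern(c(0.154, 1.346), c(0.75, 0.25), 0.15)
  nu <- nuisance_params(1)

  # r0 = 0: channels differ only by the G scale
  an0 <- anisotropy_pattern(r0 = 0, rho = 45, G = 1.3)
  vv <- model_polarized(don, fr, an0, nu, prof, "VV")
  vh <- model_polarized(don, fr, an0, nu, prof, "VH")
  expect_equal(vv, 1.3 * vh, tolerance = 1e-12)

  # G = 1 ideal: f_VV + 2 f_VH = 3 f_VM
  an1 <- anisotropy_pattern(r0 = 0.37, rho = 45, G = 1)
  vv <- model_polarized(don, fr, an1, nu, prof, "VV")
  vh <- model_polarized(don, fr, an1, nu, prof, "VH")
  expect_equal(vv + 2 * vh, 3 * model_fret(don, fr, nu, prof),
               tolerance = 1e-10)

  # VM composition cancels anisotropy for any calibrated G
  an <- anisotropy_pattern(r0 = 0.37, rho = 45, G = 1.087)
  vv <- model_polarized(don, fr, an, nu, prof, "VV")
  vh <- model_polarized(don, fr, an, nu, prof, "VH")
  vm3 <- 3 * model_fret(don, fr, nu, prof)
  expect_lt(max(abs(vv + 2 * an$G * vh - vm3) / vm3), 1e-10)

  # anisotropy decay starts at r0 and relaxes with rho
  r_t <- (vv - an$G * vh) / (vv + 2 * an$G * vh)
  expect_equal(r_t[1], 0.37 * exp(-prof$grid$times[1] / 45),
               tolerance = 1e-6)
  expect_error(model_polarized(don, fr, an, nu, prof, "XX"))
})

test_that("VM composition follows uncertainty propagation", {
  grid <- decay_grid(4, 32)
  vv <- decay_histogram(rep(100, 4), grid, "VV")
  vh <- decay_histogram(rep(50, 4), grid, "VH")
  vm <- compose_vm(vv, vh, G = 1.087)
  expect_equal(vm$counts, rep(100 + 2 * 1.087 * 50, 4))
  expect_equal(vm$counts[1], 208.7, tolerance = 1e-10)
  expect_equal(vm$weights, rep(100 + 4 * 1.087^2 * 50, 4))
  expect_equal(vm$weights[1], 336.3, tolerance = 1e-3)

  vh0 <- decay_histogram(rep(0, 4), grid, "VH")
  vm0 <- compose_vm(vv, vh0, G = 1.087)
  expect_equal(vm0$counts, vv$counts)
  expect_equal(vm0$weights, vv$counts)
  expect_equal(compose_vm(vv, vv, G = 1)$counts, 3 * vv$counts)
  expect_error(compose_vm(vv, decay_histogram(rep(1, 8), decay_grid(8, 32),
                                              "VH"), 1),
               "grid")
})

test_that("circular convolution matches the brute-force oracle", {
  # delta IRF is the identity
  x <- c(5, 1, 0.5, 0.2, rep(0, 12))
  delta <- c(1, rep(0, 15))
  expect_equal(circular_convolve(x, delta), x, tolerance = 1e-12)

  # random instances, 8 to 64 bins
  set.seed(7)
  for (n in c(8, 16, 33, 64)) {
    xi <- runif(n); irf <- runif(n); irf <- irf / sum(irf)
    expect_equal(circular_convolve(xi, irf),
                 direct_circular_convolve(xi, irf), tolerance = 1e-10)
    expect_equal(sum(circular_convolve(xi, irf)), sum(xi),
                 tolerance = 1e-10)
  }

  # one-bin shift of a delta IRF cyclically shifts the signal
  n <- 32; period <- 16; dt <- period / n
  shifted <- circular_convolve(x2 <- c(3, 2, 1, rep(0, 29)), delta2 <-
                                 c(1, rep(0, 31)), shift = dt,
                               period = period)
  expect_equal(shifted, x2[c(n, 1:(n - 1))], tolerance = 1e-9)
  expect_error(circular_convolve(1:4, 1:5), "length")
})

test_that("ideal decay integral over one period equals sum(p * tau)", {
  grid <- decay_grid(2^14, 60)
  don <- donor_pattern(c(1.68, 2.75), c(0.5, 0.5))
  integral <- sum(ideal_donor_decay(grid$times, don)) * grid$dt
  expect_equal(integral, sum(don$fractions * don$tau), tolerance = 1e-6)
})

test_that("least-squares chi-square uses Poisson weights and excludes empty bins", {
  expect_equal(chi2_ls(c(4, 9), c(4, 9), n_par = 0), 0)
  expect_equal(chi2_ls(c(4, 9), c(2, 12), n_par = 0), 1.0)
  # zero-weight bins are excluded from sum and dof
  expect_equal(chi2_ls(c(4, 0, 9), c(2, 5, 12), n_par = 0), 1.0)
  expect_error(chi2_ls(c(4, 9), c(2, 12), n_par = 2), "n_par")

  # self-consistent Poisson data has reduced chi-square near 1
  set.seed(11)
  mu <- 200 * exp(-seq(0, 5, length.out = 4000))
  d <- rpois(4000, mu)
  expect_equal(chi2_ls(d, mu, n_par = 0), 1, tolerance = 0.08)
})

test_that("Poisson deviance is zero at the data and minimized there", {
  expect_equal(chi2_ml(c(10, 3), c(10, 3)), 0)
  expect_equal(chi2_ml(10, 12), 2 * (2 + 10 * log(10 / 12)),
               tolerance = 1e-12)
  expect_equal(chi2_ml(10, 12), 0.3536, tolerance = 1e-3)
  # zero-count bins contribute model counts only
  expect_equal(chi2_ml(c(0, 5), c(2, 5)), 4)

  d <- c(7, 3, 0, 12)
  m <- c(6, 4, 1, 11)
  scales <- seq(0.5, 2, by = 0.01)
  dev <- vapply(scales, function(s) chi2_ml(d, s * m), 0)
  expect_true(all(dev >= 0))
  expect_equal(scales[which.min(dev)], sum(d) / sum(m), tolerance = 0.01)
  expect_error(chi2_ml(c(1, 2), c(0, 2)), "positive")
})
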