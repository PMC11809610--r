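# Photobleaching step analysis: KV change-point fitting, trace counts,
# regression and crowding metrics, spot selection.

test_that("minimum step size is linear and homogeneous in laser power", {
  expect_equal(min_step_size(1.36), 50)
  expect_equal(min_step_size(2.72), 100)
  expect_equal(min_step_size(0), 0)
  p <- c(0.5, 1.1, 3.7)
  expect_equal(min_step_size(2 * p), 2 * min_step_size(p))
})

test_that("KV fit finds noiseless steps at the exact change points", {
  y <- c(rep(100, 20), rep(50, 20), rep(0, 20))
  fit <- kv_step_fit(y, min_step = 20)
  expect_equal(fit$n_steps, 2)
  expect_equal(fit$changepoints, c(20, 40))
  expect_equal(fit$levels, c(100, 50, 0))
  expect_false(fit$has_upward)

  # a drop below the minimum step size is not a step
  y2 <- c(rep(100, 30), rep(70, 30))
  expect_equal(kv_step_fit(y2, min_step = 50)$n_steps, 0)
  expect_equal(kv_step_fit(y2, min_step = 20)$n_steps, 1)
  expect_error(kv_step_fit(c(1, 2, 3), min_step = 1), "4 bins")
})

test_that("greedy KV equals exhaustive SIC minimization on small traces", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(16:64, 1)
    k_true <- sample(0:2, 1)
    cps <- sort(sample(4:(n - 4), k_true))
    levels <- sort(runif(k_true + 1, 0, 300), decreasing = TRUE)
    mu <- rep(levels, diff(c(0, cps, n)))
    y <- mu + rnorm(n, 0, 8)
    min_step <- 60
    greedy <- kv_step_fit(y, min_step = min_step)
    oracle <- exhaustive_sic_fit(y, min_step = min_step, max_cp = 2)
    expect_equal(greedy$changepoints, oracle$cps,
                 info = sprintf("rep %d (n=%d, k=%d)", rep, n, k_true))
  }
})

test_that("integrated counts sum the pre-bleach photons above background", {
  y <- c(rep(100, 10), rep(0, 20))
  fit <- kv_step_fit(y, min_step = 30)
  expect_equal(integrated_counts(y, fit), 1000)
  expect_equal(fit$n_ph_int, 1000)

  flat <- rep(5, 30)
  expect_equal(kv_step_fit(flat, min_step = 30)$n_ph_int, 0)

  # background above zero is subtracted
  y3 <- c(rep(110, 10), rep(10, 20))
  fit3 <- kv_step_fit(y3, min_step = 30)
  expect_equal(integrated_counts(y3, fit3), 10 * 110 - 10 * 10)

  # monotone in brightness at fixed bleach time
  y_dim <- c(rep(60, 10), rep(0, 20))
  expect_gt(fit$n_ph_int, kv_step_fit(y_dim, min_step = 30)$n_ph_int)
})

test_that("weighted orthogonal regression matches the TLS oracle", {
  r <- steps_counts_regression(c(1, 2, 3), c(2000, 4000, 6000))
  expect_equal(r$slope, 2000, tolerance = 1e-9)
  expect_equal(r$intercept, 0, tolerance = 1e-6)

  set.seed(22)
  n_steps <- sample(1:4, 400, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
  n_ph <- 2100 * n_steps + 500 + rnorm(400, 0, 400)
  fit <- steps_counts_regression(n_steps, n_ph)
  cls <- fit$class_means
  oracle <- tls_oracle(cls$n_steps, cls$mean_n_ph, cls$n)
  expect_equal(fit$slope, oracle["slope"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(steps_counts_regression(c(1, 1), c(10, 12)), "distinct")
})

test_that("detection-conditioned step expectation and crowding factor", {
  expect_equal(expected_conditional_steps(1, 0.8), 1)
  expect_equal(expected_conditional_steps(1, 0.3), 1)
  expect_equal(expected_conditional_steps(2, 0.8), 1.6 / 0.96)
  expect_equal(expected_conditional_steps(2, 0.8), 1.667, tolerance = 1e-3)
  expect_equal(expected_conditional_steps(2, 1), 2)
  expect_error(expected_conditional_steps(2, 0))

  cm <- crowding_metrics(1.33, 1.92, eta = 0.8)
  expect_equal(cm$ratio_monomer, 1.33)
  expect_equal(cm$ratio_dimer, 1.152, tolerance = 1e-3)
  expect_equal(cm$k_crowd, 1.24, tolerance = 1e-2)
  expect_true(is.na(cm$f_no_crowd))

  ideal <- crowding_metrics(1.0, expected_conditional_steps(2, 0.8), 0.8)
  expect_equal(ideal$k_crowd, 1.0)
  expect_equal(crowding_metrics(1, 2, eta = 1)$k_crowd, 1.0)
  expect_warning(crowding_metrics(0.8, 1.2, 0.8), "below 1")
})

test_that("simulated bleach traces have the designed structure", {
  tr0 <- simulate_bleach_trace(3, brightness = 100, bleach_rate = 1,
                               background = 2, eta = 0, seed = 5)
  expect_equal(attr(tr0, "n_visible"), 0)
  expect_lt(mean(tr0$counts), 4)

  # deterministic trace with well-separated bleach times: 3 clean steps
  tr3 <- simulate_bleach_trace(3, brightness = 100, bleach_rate = 1,
                               eta = 1, seed = 8, poisson = FALSE)
  fit <- kv_step_fit(tr3, min_step = 40)
  expect_equal(fit$n_steps, attr(tr3, "n_visible"))

  # ensemble mean initial level is n * eta * brightness + background
  set.seed(30)
  lead <- replicate(300, {
    tr <- simulate_bleach_trace(2, brightness = 50, bleach_rate = 0.5,
                                background = 5, eta = 0.8)
    tr$counts[1]
  })
  expect_equal(mean(lead), 2 * 0.8 * 50 + 5, tolerance = 0.05)

  # reproducibility
  a <- simulate_bleach_trace(2, 50, 1, 3, seed = 77)
  b <- simulate_bleach_trace(2, 50, 1, 3, seed = 77)
  expect_identical(a$counts, b$counts)
})

test_that("monomer/dimer populations order as expected and crowding grows", {
  set.seed(31)
  sim_sample <- function(n_fluor, n_traces, p_coloc) {
    steps <- vapply(seq_len(n_traces), function(i) {
      n <- n_fluor + rbinom(1, 1, p_coloc)  # a second assembly in the spot
      tr <- simulate_bleach_trace(n, brightness = 120, bleach_rate = 1.5,
                                  background = 3, eta = 0.8)
      fit <- kv_step_fit(tr, min_step = 50)
      fit$n_steps
    }, 0)
    mean(steps[steps >= 1])
  }
  m0 <- sim_sample(1, 120, 0)
  d0 <- sim_sample(2, 120, 0)
  expect_gt(d0, m0)
  m_crowd <- sim_sample(1, 120, 0.35)
  d_crowd <- sim_sample(2, 120, 0.35)
  k0 <- crowding_metrics(m0, d0, 0.8)$k_crowd
  k1 <- crowding_metrics(m_crowd, d_crowd, 0.8)$k_crowd
  expect_gt(k1, k0)
})

test_that("overview spot selection enforces the separation rule", {
  expect_equal(nrow(detect_spots(matrix(0, 40, 40))), 0)
  expect_error(detect_spots(matrix(numeric(0), 0, 0)), "empty")

  img <- paint_gaussian(matrix(0, 40, 40), x0 = 20, y0 = 18,
                        amplitude = 25, sigma = 1.5)
  one <- detect_spots(img, threshold = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$x, 20)
  expect_equal(one$y, 18)

  # 300 nm apart at 50-nm pixels: both removed; 600 nm apart: both kept
  close_pair <- paint_gaussian(paint_gaussian(matrix(0, 40, 40),
                                              14, 20, 25, 1.5),
                               20, 20, 25, 1.5)
  expect_equal(nrow(detect_spots(close_pair, threshold = 4,
                                 min_separation = 450, pixel_size = 50)),
               0)
  far_pair <- paint_gaussian(paint_gaussian(matrix(0, 40, 40),
                                            12, 20, 25, 1.5),
                             24, 20, 25, 1.5)
  expect_equal(nrow(detect_spots(far_pair, threshold = 4,
                                 min_separation = 450, pixel_size = 50)),
               2)
})
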