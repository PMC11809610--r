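# Shared fixtures and independent oracles used across the suite.

# brute-force O(N^2) circular convolution
direct_circular_convolve <- function(x, irf) {
  n <- length(x)
  vapply(0:(n - 1), function(i)
    sum(x * irf[((i - 0:(n - 1)) %% n) + 1]), 0)
}

# exhaustive SIC minimization over all piecewise-constant fits with up to
# `max_cp` change points, subject to every adjacent level difference
# being at least `min_step`
exhaustive_sic_fit <- function(y, min_step, max_cp = 2) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  seg_rss <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  seg_mean <- function(i, j) (cs[j + 1] - cs[i]) / (j - i + 1)
  sic <- function(rss, k) (k + 2) * log(n) + n * log(max(rss / n, 1e-12))
  eval_cps <- function(cps) {
    b <- c(0, cps, n)
    mus <- numeric(length(b) - 1); rss <- 0
    for (s in seq_len(length(b) - 1)) {
      mus[s] <- seg_mean(b[s] + 1, b[s + 1])
      rss <- rss + seg_rss(b[s] + 1, b[s + 1])
    }
    if (length(mus) > 1 && any(abs(diff(mus)) < min_step)) return(NULL)
    list(cps = cps, sic = sic(rss, length(cps)), levels = mus)
  }
  best <- eval_cps(integer(0))
  if (max_cp >= 1)
    for (c1 in 1:(n - 1)) {
      cand <- eval_cps(c1)
      if (!is.null(cand) && cand$sic < best$sic) best <- cand
    }
  if (max_cp >= 2 && n >= 3)
    for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
      cand <- eval_cps(c(c1, c2))
      if (!is.null(cand) && cand$sic < best$sic) best <- cand
    }
  best
}

# orthogonal (total least squares) regression through weighted class
# means by direct numerical minimization of perpendicular distances
tls_oracle <- function(x, y, w) {
  obj <- function(p) sum(w * (y - p[1] - p[2] * x)^2 / (1 + p[2]^2))
  ls <- coef(lm(y ~ x, weights = w))
  fit <- optim(c(ls[1], ls[2]), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  c(intercept = unname(fit$par[1]), slope = unname(fit$par[2]))
}

# sample apoptosis event times from a Hill cumulative curve with
# p_min = 0 by CDF inversion
sample_hill_events <- function(n_cells, p_max, t_half, hill_n) {
  dies <- runif(n_cells) < p_max
  u <- runif(sum(dies))
  t_half * (u / (1 - u))^(1 / hill_n)
}

# small Gaussian blob painted onto an image matrix (row = y, col = x)
paint_gaussian <- function(img, x0, y0, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  ys <- matrix(seq_len(nr), nr, nc)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img + amplitude * exp(-0.5 * (((xs - x0)^2 + (ys - y0)^2) / sigma^2))
}

test_instrument <- function(n_bins = 512, G = 1.087)
  synthetic_instrument(n_bins = n_bins, period = 32, G = G)

test_library <- function() default_pattern_library()
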