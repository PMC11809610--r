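# Confocal photobleaching step analysis: spots are picked on a smoothed
# overview image, a photon trace is recorded per spot, and discrete
# bleaching steps are counted with the Kalafut-Visscher change-point
# detector (Schwarz information criterion over piecewise-constant fits,
# minimal step size as the sole user input).

#' Photobleaching photon trace
#'
#' @param counts Photon counts per time bin.
#' @param t_bin Bin width in seconds (default 5 ms).
#' @param p485 Excitation laser power in microwatts (485 nm line); used
#'   to derive the minimum step size.
#' @return A `bleach_trace` object.
#' @export
bleach_trace <- function(counts, t_bin = 0.005, p485 = 1.36) {
  stopifnot(all(counts >= 0), t_bin > 0, p485 >= 0)
  structure(list(counts = as.numeric(counts), t_bin = t_bin, p485 = p485),
            class = "bleach_trace")
}

#' Minimum bleaching-step size for a given excitation power
#'
#' The step-size threshold separating real bleaching events from noise
#' scales linearly with excitation power: `50 * p485 / 1.36` counts per
#' bin, anchored at 50 counts per 5-ms bin (10 kHz) at 1.36 uW.
#'
#' @param p485 Laser power in microwatts, `>= 0`.
#' @return Threshold in counts per bin.
#' @examples
#' min_step_size(1.36)  # 50 counts / 5 ms = 10 kHz
#' @export
min_step_size <- function(p485) {
  stopifnot(all(p485 >= 0))
  50 * p485 / 1.36
}

# segment RSS of y[i..j] from cumulative sums: sum(y^2) - sum(y)^2/n
.seg_rss <- function(cs, cs2, i, j) {
  s <- cs[j + 1] - cs[i]
  s2 <- cs2[j + 1] - cs2[i]
  s2 - s^2 / (j - i + 1)
}

.sic <- function(rss, n, k) {
  sigma2 <- max(rss / n, 1e-12)
  (k + 2) * log(n) + n * log(sigma2)
}

.levels_from_cps <- function(y, cps) {
  # cps: indices of the last bin of each segment except the final one
  b <- c(0, cps, length(y))
  vapply(seq_len(length(b) - 1),
         function(s) mean(y[(b[s] + 1):b[s + 1]]), 0)
}

#' Kalafut-Visscher change-point step fit
#'
#' Greedy forward change-point addition on a piecewise-constant model,
#' accepting a split only while the Schwarz information criterion
#' `SIC = (k + 2) ln N + N ln(RSS/N)` decreases, and only when the level
#' difference across the new boundary is at least `min_step`. Bleaching
#' steps `n_steps` are the downward level transitions; upward transitions
#' (blinking or a second molecule entering the focus) are fitted but only
#' flagged.
#'
#' @param trace A [bleach_trace()] or numeric count vector (at least 4
#'   bins).
#' @param min_step Minimum accepted level difference in counts per bin;
#'   defaults to [min_step_size()] at the trace's laser power.
#' @return A `step_fit` list: `n_steps`, `changepoints` (last bin index
#'   of each segment but the final one), `levels` (segment means),
#'   `background` (final level), `n_ph_int` (see
#'   [integrated_counts()]), `has_upward`, `min_step`, `sic`.
#' @export
kv_step_fit <- function(trace, min_step = NULL) {
  y <- if (inherits(trace, "bleach_trace")) trace$counts else as.numeric(trace)
  if (length(y) < 4) stop("trace must have at least 4 bins")
  if (is.null(min_step)) {
    if (!inherits(trace, "bleach_trace"))
      stop("min_step is required for a bare numeric trace")
    min_step <- min_step_size(trace$p485)
  }
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  cps <- integer(0)
  rss <- .seg_rss(cs, cs2, 1, n)
  sic <- .sic(rss, n, 0)
  repeat {
    bounds <- c(0, cps, n)
    best <- NULL
    for (s in seq_len(length(bounds) - 1)) {
      lo <- bounds[s] + 1; hi <- bounds[s + 1]
      if (hi - lo < 1) next
      seg_rss <- .seg_rss(cs, cs2, lo, hi)
      for (cp in lo:(hi - 1)) {
        mu_l <- (cs[cp + 1] - cs[lo]) / (cp - lo + 1)
        mu_r <- (cs[hi + 1] - cs[cp + 1]) / (hi - cp)
        if (abs(mu_l - mu_r) < min_step) next
        new_rss <- rss - seg_rss +
          .seg_rss(cs, cs2, lo, cp) + .seg_rss(cs, cs2, cp + 1, hi)
        if (is.null(best) || new_rss < best$rss)
          best <- list(cp = cp, rss = new_rss)
      }
    }
    if (is.null(best)) break
    new_sic <- .sic(best$rss, n, length(cps) + 1)
    if (new_sic >= sic) break
    cps <- sort(c(cps, best$cp))
    rss <- best$rss
    sic <- new_sic
  }
  levels <- .levels_from_cps(y, cps)
  dl <- diff(levels)
  fit <- structure(
    list(n_steps = sum(dl < 0), changepoints = cps, levels = levels,
         background = levels[length(levels)],
         has_upward = any(dl > 0), min_step = min_step, sic = sic,
         n_ph_int = NA_real_),
    class = "step_fit")
  fit$n_ph_int <- integrated_counts(y, fit)
  fit
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d bleaching step(s), levels %s, N_Ph,int = %.0f\n",
              x$n_steps, paste(sprintf("%.1f", x$levels), collapse = " > "),
              x$n_ph_int))
  invisible(x)
}

#' Integrated photon count of a bleaching trace
#'
#' Total photons collected from the trace start until the final downward
#' (bleaching) transition, with the fitted background level (the final
#' segment mean) subtracted. Zero when no bleaching step was detected.
#'
#' @param trace A [bleach_trace()] or numeric count vector.
#' @param fit A [kv_step_fit()] result for that trace.
#' @return The integrated count `N_Ph,int` (non-negative).
#' @export
integrated_counts <- function(trace, fit) {
  y <- if (inherits(trace, "bleach_trace")) trace$counts else as.numeric(trace)
  dl <- diff(fit$levels)
  down <- which(dl < 0)
  if (length(down) == 0) return(0)
  last_cp <- fit$changepoints[max(down)]
  max(sum(y[seq_len(last_cp)]) - fit$background * last_cp, 0)
}

#' Weighted orthogonal regression of trace counts on step number
#'
#' Regresses the mean integrated photon count per step-number class on
#' the step number by total least squares (orthogonal residuals),
#' weighting each class mean by its population count. The slope estimates
#' the photon budget of a single fluorophore (counts per step).
#'
#' @param n_steps Per-trace step counts.
#' @param n_ph Per-trace integrated photon counts.
#' @param drop_zero Exclude traces without detected steps (default TRUE).
#' @return A list with `slope` (counts per step), `intercept`, and
#'   `class_means` (the weighted means per step number).
#' @export
steps_counts_regression <- function(n_steps, n_ph, drop_zero = TRUE) {
  stopifnot(length(n_steps) == length(n_ph))
  if (drop_zero) {
    keep <- n_steps > 0
    n_steps <- n_steps[keep]; n_ph <- n_ph[keep]
  }
  cls <- sort(unique(n_steps))
  if (length(cls) < 2)
    stop("need at least two distinct step numbers for a regression")
  x <- cls
  ybar <- vapply(cls, function(k) mean(n_ph[n_steps == k]), 0)
  w <- vapply(cls, function(k) sum(n_steps == k), 0)
  xm <- sum(w * x) / sum(w); ym <- sum(w * ybar) / sum(w)
  sxx <- sum(w * (x - xm)^2); syy <- sum(w * (ybar - ym)^2)
  sxy <- sum(w * (x - xm) * (ybar - ym))
  slope <- if (abs(sxy) < 1e-300) 0 else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = ym - slope * xm,
       class_means = data.frame(n_steps = x, mean_n_ph = ybar, n = w))
}

#' Expected visible step number of an n-mer, conditioned on detection
#'
#' With per-fluorophore maturation probability `eta`, the number of
#' visible fluorophores in an n-mer is Binomial(n, eta); spots are only
#' recorded when at least one fluorophore is visible, so the relevant
#' expectation is `E[K | K >= 1] = n eta / (1 - (1 - eta)^n)`.
#'
#' @param n Number of fluorophores in the assembly, `>= 1`.
#' @param eta Maturation (visibility) probability in (0, 1\].
#' @return The conditional expected step number.
#' @examples
#' expected_conditional_steps(2, 0.8)  # ~1.667 for a pseudo-dimer
#' @export
expected_conditional_steps <- function(n, eta) {
  stopifnot(all(n >= 1), all(eta > 0), all(eta <= 1))
  n * eta / (1 - (1 - eta)^n)
}

#' Molecular crowding factor from monomer and pseudo-dimer controls
#'
#' Co-localization of independent molecules inside one diffraction-limited
#' spot inflates the observed mean step number above the
#' maturation-corrected ideal expectation. The per-sample crowding ratio
#' is observed / expected (with [expected_conditional_steps()] as the
#' ideal), and the summary crowding factor is the average of the monomer
#' and pseudo-dimer ratios. Values below 1 are physically unexpected and
#' flagged. The fraction of crowding-unaffected receptors `f_no_crowd`
#' requires a spot-occupancy model not implemented here and is returned
#' as `NA`.
#'
#' @param mean_steps_monomer Observed mean step number of the monomer
#'   control.
#' @param mean_steps_dimer Observed mean step number of the pseudo-dimer
#'   control.
#' @param eta Fluorophore maturation efficiency (default 0.8).
#' @return A list with `ratio_monomer`, `ratio_dimer`, `k_crowd`,
#'   `f_no_crowd` (`NA`) and `subideal` (TRUE when k_crowd < 1).
#' @examples
#' crowding_metrics(1.33, 1.92, eta = 0.8)$k_crowd  # ~1.24
#' @export
crowding_metrics <- function(mean_steps_monomer, mean_steps_dimer,
                             eta = 0.8) {
  r1 <- mean_steps_monomer / expected_conditional_steps(1, eta)
  r2 <- mean_steps_dimer / expected_conditional_steps(2, eta)
  k <- mean(c(r1, r2))
  if (k < 1) warning("crowding factor below 1: check the input means")
  list(ratio_monomer = r1, ratio_dimer = r2, k_crowd = k,
       f_no_crowd = NA_real_, subideal = k < 1)
}

#' Simulate a photobleaching trace
#'
#' Each of `n` fluorophores is independently visible with probability
#' `eta`; visible fluorophores bleach at exponentially distributed times
#' with rate `bleach_rate`. Per-bin counts are Poisson around the current
#' level (brightness times the occupancy fraction of the bin) plus
#' background. Reproducible under `seed`.
#'
#' @param n Number of fluorophores in the assembly.
#' @param brightness Expected counts per bin per visible fluorophore.
#' @param bleach_rate Bleaching rate in 1/s.
#' @param background Background counts per bin.
#' @param eta Maturation (visibility) probability (default 0.8).
#' @param t_bin Bin width in s (default 5 ms).
#' @param duration Trace duration in s (default 3).
#' @param p485 Laser power recorded with the trace (default 1.36 uW).
#' @param seed Optional integer seed.
#' @param poisson Apply Poisson noise (default TRUE); with `FALSE` the
#'   deterministic expected trace is returned (useful for oracles).
#' @return A [bleach_trace()] with attributes `n_visible` and
#'   `bleach_times`.
#' @export
simulate_bleach_trace <- function(n, brightness, bleach_rate, background = 0,
                                  eta = 0.8, t_bin = 0.005, duration = 3,
                                  p485 = 1.36, seed = NULL, poisson = TRUE) {
  stopifnot(n >= 0, brightness >= 0, bleach_rate > 0, background >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_bins <- ceiling(duration / t_bin)
  visible <- if (n > 0) runif(n) < eta else logical(0)
  tb <- rexp(sum(visible), rate = bleach_rate)
  edges <- seq_len(n_bins) * t_bin
  level <- numeric(n_bins)
  for (t_die in tb) {
    # bleach times are discretized to bin boundaries (negligible at 5-ms
    # bins); a fluorophore contributes while alive through the whole bin
    level <- level + brightness * as.numeric(t_die >= edges)
  }
  mu <- level + background
  counts <- if (poisson) rpois(n_bins, mu) else mu
  out <- bleach_trace(counts, t_bin = t_bin, p485 = p485)
  attr(out, "n_visible") <- sum(visible)
  attr(out, "bleach_times") <- tb
  out
}

# ---- overview-image spot selection ----------------------------------------

#' Detect well-separated molecular assemblies on an overview image
#'
#' Smooths the photon-count image with a Gaussian filter (sigma 1 px),
#' finds local maxima exceeding the count threshold, and discards every
#' maximum that lies closer than `min_separation` to any other maximum
#' (both members of a close pair are removed), so that each retained spot
#' can be bleached without exciting a neighbor.
#'
#' @param image Photon-count matrix (rows = y, columns = x).
#' @param threshold Count threshold on the smoothed image, conventionally
#'   3 to 5 (default 4).
#' @param min_separation Minimum pairwise distance in nm (default 450).
#' @param pixel_size Pixel size in nm (default 50).
#' @param smooth_sigma Gaussian smoothing sigma in px (default 1).
#' @return A data.frame with `x`, `y` (pixel coordinates, 1-based column
#'   and row) and `value` (smoothed counts at the maximum).
#' @export
detect_spots <- function(image, threshold = 4, min_separation = 450,
                         pixel_size = 50, smooth_sigma = 1) {
  if (length(image) == 0) stop("empty image")
  stopifnot(threshold >= 0, min_separation >= 0, pixel_size > 0)
  sm <- gaussian_smooth(image, smooth_sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  maxima <- NULL
  if (nr >= 3 && nc >= 3) {
    core <- sm[2:(nr - 1), 2:(nc - 1)]
    is_max <- core > threshold
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
      is_max <- is_max & (core >= nb)
      # strict on the lexicographically earlier neighbor to break plateaus
      if (dr < 0 || (dr == 0 && dc < 0)) is_max <- is_max & (core > nb)
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0)
      maxima <- data.frame(y = idx[, 1] + 1, x = idx[, 2] + 1,
                           value = sm[cbind(idx[, 1] + 1, idx[, 2] + 1)])
  }
  if (is.null(maxima) || nrow(maxima) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  if (nrow(maxima) > 1 && min_separation > 0) {
    d <- as.matrix(dist(maxima[, c("x", "y")])) * pixel_size
    diag(d) <- Inf
    keep <- apply(d, 1, min) >= min_separation
    maxima <- maxima[keep, , drop = FALSE]
  }
  rownames(maxima) <- NULL
  maxima[, c("x", "y", "value")]
}
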