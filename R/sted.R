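# Quantitative STED-like spot analysis: composite images of simulated
# oligomer spots (2D Gaussians with brightness dispersion and Poisson
# noise), threshold/connected-component spot detection with 2D Gaussian
# refinement, pair-correlation statistics and steady-state anisotropy.

#' Configuration of a composite spot-image simulation
#'
#' @param n_objects Number of objects stamped into the image (default
#'   10000 at full scale; use fewer for desk-scale runs).
#' @param image_size Side length of the square image in px (default 2500).
#' @param n_fluor Fluorophores per object: 1 monomer, 2 dimer, 3 trimer,
#'   6 dimer-of-trimers.
#' @param q_mean Mean peak amplitude Q of one fluorophore's Gaussian, in
#'   photons.
#' @param q_sd SD of the normal amplitude dispersion (default
#'   `0.3 * q_mean`, the brightness variation caused by random dipole
#'   orientations).
#' @param sigma_px Gaussian spot SD in px (default 2.5, a
#'   diffraction-limited STED spot at 10-nm pixels).
#' @param bg_mean Mean of the Poisson background per pixel (default 0.2).
#' @param labeling Per-fluorophore labeling/maturation probability
#'   (default 1, appropriate for an organic-dye nanobody channel; use 0.8
#'   for fluorescent-protein constructs).
#' @param stamp_size Side of the per-object stamp in px (default 25).
#' @param seed Integer seed.
#' @return A `sted_sim_config` object.
#' @export
sted_sim_config <- function(n_objects = 10000, image_size = 2500,
                            n_fluor = 1, q_mean = 5, q_sd = 0.3 * q_mean,
                            sigma_px = 2.5, bg_mean = 0.2, labeling = 1,
                            stamp_size = 25, seed = 1) {
  stopifnot(n_objects > 0, image_size >= stamp_size, n_fluor >= 1,
            q_mean > 0, q_sd >= 0, sigma_px > 0, bg_mean >= 0,
            labeling > 0, labeling <= 1)
  structure(list(n_objects = as.integer(n_objects),
                 image_size = as.integer(image_size),
                 n_fluor = as.integer(n_fluor), q_mean = q_mean,
                 q_sd = q_sd, sigma_px = sigma_px, bg_mean = bg_mean,
                 labeling = labeling, stamp_size = as.integer(stamp_size),
                 seed = as.integer(seed)),
            class = "sted_sim_config")
}

.unit_gaussian_stamp <- function(stamp_size, sigma) {
  c0 <- (stamp_size + 1) / 2
  g1 <- exp(-0.5 * ((seq_len(stamp_size) - c0) / sigma)^2)
  outer(g1, g1)
}

#' Simulate a composite image of oligomer spots
#'
#' Stamps `n_objects` spots into a zero image: each object carries
#' `n_fluor` coincident 2D Gaussians (sub-resolution oligomer) whose peak
#' amplitudes are drawn normally around `q_mean` with SD `q_sd`
#' (truncated at zero) and which are visible with probability `labeling`.
#' Poisson noise is applied to the stamp counts, stamps are added at
#' uniform random integer coordinates (objects fully inside the image),
#' and a Poisson background of mean `bg_mean` is added per pixel.
#' Bit-identical under the same seed.
#'
#' @param config A [sted_sim_config()].
#' @param poisson Apply the Poisson noise stages (default TRUE; `FALSE`
#'   gives the deterministic expected image, useful for oracles).
#' @return A list with `image` (integer count matrix, rows = y) and
#'   `objects` (data.frame `x`, `y` of stamp-center coordinates,
#'   `n_visible`, `q_total`).
#' @export
simulate_composite_image <- function(config, poisson = TRUE) {
  stopifnot(inherits(config, "sted_sim_config"))
  set.seed(config$seed)
  s <- config$stamp_size
  size <- config$image_size
  img <- matrix(0, size, size)
  unit <- .unit_gaussian_stamp(s, config$sigma_px)
  half <- (s - 1) / 2
  x0 <- sample.int(size - s + 1, config$n_objects, replace = TRUE)
  y0 <- sample.int(size - s + 1, config$n_objects, replace = TRUE)
  n_visible <- integer(config$n_objects)
  q_total <- numeric(config$n_objects)
  for (i in seq_len(config$n_objects)) {
    vis <- runif(config$n_fluor) < config$labeling
    k <- sum(vis)
    n_visible[i] <- k
    if (k == 0) next
    q <- pmax(rnorm(k, config$q_mean, config$q_sd), 0)
    q_total[i] <- sum(q)
    stamp <- sum(q) * unit
    if (poisson) stamp <- matrix(rpois(s * s, stamp), s, s)
    ry <- y0[i]:(y0[i] + s - 1); rx <- x0[i]:(x0[i] + s - 1)
    img[ry, rx] <- img[ry, rx] + stamp
  }
  if (config$bg_mean > 0 && poisson)
    img <- img + matrix(rpois(size * size, config$bg_mean), size, size)
  else if (config$bg_mean > 0)
    img <- img + config$bg_mean
  list(image = img,
       objects = data.frame(x = x0 + half, y = y0 + half,
                            n_visible = n_visible, q_total = q_total))
}

#' Gaussian smoothing of a count image
#'
#' Separable Gaussian filter with reflective boundary handling; thin
#' wrapper used by the spot detectors.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian SD in px.
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1), n)
  smooth1 <- function(m) {
    p <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * p[seq_len(nrow(m)) + (j - 1), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(image))))
}

.fit_gaussian_window <- function(win) {
  n <- nrow(win)
  xs <- rep(seq_len(n), each = n); ys <- rep(seq_len(n), n)
  z <- as.numeric(win[cbind(ys, xs)])
  off0 <- min(z); a0 <- max(z) - off0
  wpos <- pmax(z - off0, 0) + 1e-9
  x0 <- sum(wpos * xs) / sum(wpos); y0 <- sum(wpos * ys) / sum(wpos)
  res_fn <- function(p) {
    a <- p[1]; xc <- p[2]; yc <- p[3]
    sx <- exp(p[4]); sy <- exp(p[5]); off <- p[6]
    a * exp(-0.5 * (((xs - xc) / sx)^2 + ((ys - yc) / sy)^2)) + off - z
  }
  fit <- try(nls.lm(par = c(max(a0, 1e-6), x0, y0, log(2), log(2), off0),
                    fn = res_fn,
                    control = nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(converged = FALSE))
  p <- fit$par
  list(converged = fit$info %in% 1:4, amplitude = p[1],
       x = p[2], y = p[3], sigma_x = exp(p[4]), sigma_y = exp(p[5]),
       offset = p[6], rss = sum(fit$fvec^2))
}

#' Detect and characterize spots in a count image
#'
#' Thresholds the image (default: every pixel with at least one photon),
#' labels connected regions, keeps regions of at least `min_size` pixels,
#' and refines each region's intensity-weighted center by least-squares
#' fitting of an elliptical 2D Gaussian on a `window` x `window` patch of
#' the raw image. Reported per spot: the geometric-mean SD
#' `sigma = sqrt(sigma_x * sigma_y)`, the fitted peak amplitude, and the
#' mean photons per pixel over the fit window. Spots whose fit window
#' would cross the image border are dropped. An image without spots
#' yields an empty table.
#'
#' @param image Photon-count matrix (rows = y).
#' @param threshold Detection threshold in photons (default 1).
#' @param min_size Minimum connected-region area in px (default 9).
#' @param window Gaussian fit window side in px (odd, default 11).
#' @return A data.frame with one row per spot: `x`, `y`, `sigma`,
#'   `sigma_x`, `sigma_y`, `amplitude`, `n_ph_mean`, `offset`, `area`,
#'   `rss`, `converged`.
#' @export
analyze_spots <- function(image, threshold = 1, min_size = 9, window = 11) {
  if (length(image) == 0) stop("empty image")
  stopifnot(window %% 2 == 1)
  empty <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      sigma_x = numeric(0), sigma_y = numeric(0),
                      amplitude = numeric(0), n_ph_mean = numeric(0),
                      offset = numeric(0), area = integer(0),
                      rss = numeric(0), converged = logical(0))
  mask <- image >= threshold
  if (!any(mask)) return(empty)
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  n_lab <- max(labels)
  if (n_lab == 0) return(empty)
  areas <- tabulate(labels[labels > 0], nbins = n_lab)
  keep <- which(areas >= min_size)
  if (length(keep) == 0) return(empty)
  half <- (window - 1) %/% 2
  nr <- nrow(image); nc <- ncol(image)
  rows <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    lab <- keep[ii]
    px <- which(labels == lab, arr.ind = TRUE)
    wts <- image[px]
    cy <- round(sum(px[, 1] * wts) / sum(wts))
    cx <- round(sum(px[, 2] * wts) / sum(wts))
    if (cy - half < 1 || cy + half > nr || cx - half < 1 || cx + half > nc)
      next
    win <- image[(cy - half):(cy + half), (cx - half):(cx + half)]
    f <- .fit_gaussian_window(win)
    if (!isTRUE(f$converged)) next
    rows[[ii]] <- data.frame(
      x = cx - half - 1 + f$x, y = cy - half - 1 + f$y,
      sigma = sqrt(f$sigma_x * f$sigma_y),
      sigma_x = f$sigma_x, sigma_y = f$sigma_y,
      amplitude = f$amplitude, n_ph_mean = mean(win),
      offset = f$offset, area = areas[lab], rss = f$rss,
      converged = TRUE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- pair correlation ------------------------------------------------------

# isotropized set covariance of an a x b rectangle (valid for r <= min(a, b))
.rect_gamma <- function(r, a, b) {
  pmax(a * b - 2 * r * (a + b) / pi + r^2 / pi, 0)
}

#' Pair-correlation function of planar spot centers
#'
#' Kernel-smoothed isotropic pair-correlation estimator
#' \eqn{g(r) = \frac{1}{\pi \rho^2 r \gamma(r)} \sum_{i<j} k(r - |p_i - p_j|)}
#' with an Epanechnikov kernel of the given bandwidth and the isotropized
#' set covariance \eqn{\gamma(r)} of the rectangular observation window
#' as border correction. Equals 1 for complete spatial randomness. When a
#' list of point sets is given the per-image estimates are averaged.
#'
#' @param points A two-column matrix/data.frame of (x, y) coordinates, or
#'   a list of such sets sharing the window.
#' @param window Observation window `c(xmin, xmax, ymin, ymax)` in the
#'   same units as the coordinates.
#' @param r_max Largest distance evaluated (default a quarter of the
#'   shorter window side).
#' @param bin_width Distance bin width (default 10, nm when coordinates
#'   are in nm).
#' @param bandwidth Kernel bandwidth (default 5).
#' @return A data.frame with `r` (bin centers) and `g`.
#' @export
pair_correlation <- function(points, window, r_max = NULL,
                             bin_width = 10, bandwidth = 5) {
  if (is.list(points) && !is.data.frame(points) && !is.matrix(points)) {
    gs <- lapply(points, pair_correlation, window = window, r_max = r_max,
                 bin_width = bin_width, bandwidth = bandwidth)
    out <- gs[[1]]
    out$g <- rowMeans(do.call(cbind, lapply(gs, `[[`, "g")))
    return(out)
  }
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2) stop("need at least two points")
  a <- window[2] - window[1]; b <- window[4] - window[3]
  stopifnot(a > 0, b > 0)
  if (is.null(r_max)) r_max <- min(a, b) / 4
  rc <- seq(bin_width / 2, r_max, by = bin_width)
  n <- nrow(pts)
  area <- a * b
  rho2 <- n * (n - 1) / area^2
  ksum <- numeric(length(rc))
  # chunked pairwise distances to bound memory
  chunk <- max(1L, floor(2e7 / n))
  i <- 1L
  while (i <= n - 1) {
    hi <- min(i + chunk - 1L, n - 1L)
    for (ii in i:hi) {
      dx <- pts[(ii + 1):n, 1] - pts[ii, 1]
      dy <- pts[(ii + 1):n, 2] - pts[ii, 2]
      d <- sqrt(dx * dx + dy * dy)
      d <- d[d <= r_max + bandwidth]
      if (length(d) == 0) next
      for (k in seq_along(rc)) {
        u <- (rc[k] - d) / bandwidth
        inside <- abs(u) < 1
        if (any(inside))
          ksum[k] <- ksum[k] +
            sum(0.75 * (1 - u[inside]^2) / bandwidth)
      }
    }
    i <- hi + 1L
  }
  g <- ksum / (pi * rho2 * rc * .rect_gamma(rc, a, b))
  data.frame(r = rc, g = g)
}

#' Steady-state fluorescence anisotropy
#'
#' \eqn{r = (I_P - G I_S) / (I_P + 2 G I_S)} from the parallel and
#' perpendicular spot intensities, with the polarization correction
#' factor G for the instrument's polarization-dependent transmission.
#'
#' @param i_p Parallel-channel intensity.
#' @param i_s Perpendicular-channel intensity.
#' @param G Polarization correction factor (default 1.087).
#' @return Anisotropy value(s).
#' @export
steady_state_anisotropy <- function(i_p, i_s, G = 1.087) {
  denom <- i_p + 2 * G * i_s
  if (any(denom <= 0)) stop("non-positive total intensity")
  (i_p - G * i_s) / denom
}
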