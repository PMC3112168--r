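#' Generate a synthetic punctum field
#'
#' Places `n` non-overlapping particles uniformly on a frame by hard-core
#' rejection sampling, with integer pixel^2 areas drawn from a configurable
#' size distribution. The field is the ground truth for the image-rendering /
#' particle-detection round trip: `c_t` equals the sum of the sampled areas
#' exactly.
#'
#' @param n number of particles (>= 0).
#' @param mean_area mean particle area (pixel^2).
#' @param dispersion dispersion of the size distribution: `sdlog` for the
#'   lognormal family, coefficient of variation for gamma; ignored for
#'   `"fixed"`.
#' @param family size-distribution family: `"lognormal"` (default), `"gamma"`
#'   or `"fixed"` (all areas equal to `mean_area`). Draws are rounded to
#'   integers and floored at 1 pixel^2.
#' @param frame frame dimensions `c(height, width)` in pixels.
#' @param min_separation minimum centre-to-centre distance (pixels) between
#'   particles (hard core). 0 disables the constraint.
#' @param peak_intensity peak (per-pixel) intensity of each particle, a.u.
#' @param peak_cv coefficient of variation of per-particle peak intensity
#'   (lognormal); 0 means identical peaks.
#' @param max_attempts total rejection-sampling budget; defaults to `100 * n`.
#' @param seed integer seed; all randomness is reproducible given it.
#'
#' @return A [particle_set()].
#' @export
generate_particle_field <- function(n, mean_area = 20, dispersion = 0.4,
                                    family = c("lognormal", "gamma", "fixed"),
                                    frame = c(512L, 512L), min_separation = 0,
                                    peak_intensity = 800, peak_cv = 0,
                                    max_attempts = NULL, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 0, mean_area >= 1, length(frame) == 2L)
  if (is.null(max_attempts)) max_attempts <- max(100L * n, 100L)
  gen <- function() {
    areas <- switch(family,
      lognormal = stats::rlnorm(n, meanlog = log(mean_area) - dispersion^2 / 2,
                                sdlog = dispersion),
      gamma = stats::rgamma(n, shape = 1 / dispersion^2,
                            scale = mean_area * dispersion^2),
      fixed = rep(mean_area, n))
    areas <- pmax(1, round(areas))
    peaks <- if (peak_cv > 0) {
      stats::rlnorm(n, meanlog = log(peak_intensity) - log(1 + peak_cv^2) / 2,
                    sdlog = sqrt(log(1 + peak_cv^2)))
    } else rep(peak_intensity, n)
    # margin keeps the whole rasterised blob inside the frame
    margin <- ceiling(sqrt(max(areas, 1))) + 2
    if (2 * margin >= min(frame)) stop("frame too small for the requested areas")
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L; attempts <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("particle placement infeasible: rejection-sampling budget (",
             max_attempts, " attempts) exhausted after placing ", placed,
             " of ", n, " particles")
      }
      x <- stats::runif(1, margin + 1, frame[2] - margin)
      y <- stats::runif(1, margin + 1, frame[1] - margin)
      if (min_separation > 0 && placed > 0L) {
        d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
        if (min(d2) < min_separation^2) next
      }
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
    particle_set(data.frame(x = xs, y = ys, area = areas, peak = peaks), frame)
  }
  if (n == 0L) {
    return(particle_set(NULL, frame))
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

# Rasterise one particle: the round(area) pixels nearest the centroid.
# Deterministic tie-break: distance, then column-major pixel index.
rasterise_particle <- function(x, y, area, dim) {
  a <- max(1L, as.integer(round(area)))
  r <- ceiling(sqrt(a / pi)) + 2L
  cx <- round(x); cy <- round(y)
  cols <- max(1L, cx - r):min(dim[2], cx + r)
  rows <- max(1L, cy - r):min(dim[1], cy + r)
  g <- expand.grid(row = rows, col = cols)
  d2 <- (g$col - x)^2 + (g$row - y)^2
  ord <- order(d2, (g$col - 1L) * dim[1] + g$row)
  pick <- g[ord[seq_len(a)], ]
  (pick$col - 1L) * dim[1] + pick$row
}

# Separable Gaussian blur with a normalised kernel (sum 1); blobs are kept
# away from the frame border by the generator's margin, so zero padding does
# not lose signal in practice.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  band <- function(nn) {
    b <- matrix(0, nn, nn)
    for (off in -r:r) {
      idx <- seq_len(nn - abs(off))
      if (off >= 0) b[cbind(idx + off, idx)] <- k[off + r + 1]
      else b[cbind(idx, idx - off)] <- k[off + r + 1]
    }
    b
  }
  band(nrow(mat)) %*% mat %*% t(band(ncol(mat)))
}

#' Render a punctum field as a fluorescence image
#'
#' Each particle is drawn as a compact pixel set of exactly `round(area)`
#' pixels at its peak intensity, optionally blurred by a Gaussian PSF
#' (normalised kernel, so integrated intensity is preserved), on a constant
#' background. Noise follows the standard fluorescence camera model: Poisson
#' shot noise on signal + background, then additive Gaussian read noise.
#' With `psf_sigma = 0` and noise off, each particle's integrated intensity
#' above background equals `area * peak` exactly.
#'
#' @param field a [particle_set()].
#' @param psf_sigma Gaussian PSF standard deviation, pixels (>= 0).
#' @param background constant background intensity, a.u.
#' @param noise noise model: `"none"`, `"poisson"` (shot noise only) or
#'   `"poisson_gaussian"` (shot + read noise).
#' @param read_noise_sd Gaussian read-noise standard deviation, a.u.
#' @param pixel_size micrometres per pixel (metadata only).
#' @param seed integer seed for the noise draws.
#'
#' @return A [fluorescence_image()]; `meta` records the rendering calibration
#'   (psf_sigma, background, noise model, seed) and the ground-truth field.
#' @export
render_image <- function(field, psf_sigma = 1, background = 100,
                         noise = c("none", "poisson", "poisson_gaussian"),
                         read_noise_sd = 5, pixel_size = 0.1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(field, "particle_set"), psf_sigma >= 0, background >= 0)
  dim <- field$dim
  canvas <- matrix(0, dim[1], dim[2])
  p <- field$particles
  if (field$n_t > 0) {
    for (i in seq_len(field$n_t)) {
      idx <- rasterise_particle(p$x[i], p$y[i], p$area[i], dim)
      canvas[idx] <- canvas[idx] + p$peak[i]
    }
  }
  canvas <- gaussian_blur(canvas, psf_sigma) + background
  apply_noise <- function() {
    out <- canvas
    if (noise %in% c("poisson", "poisson_gaussian")) {
      out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)),
                    nrow(out), ncol(out))
    }
    if (noise == "poisson_gaussian" && read_noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = read_noise_sd),
                          nrow(out), ncol(out))
    }
    pmax(out, 0)
  }
  px <- if (noise == "none") canvas
        else if (!is.null(seed)) withr::with_seed(seed, apply_noise())
        else apply_noise()
  fluorescence_image(px, pixel_size = pixel_size,
                     meta = list(psf_sigma = psf_sigma, background = background,
                                 noise = noise, read_noise_sd = read_noise_sd,
                                 seed = seed, ground_truth = field))
}
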