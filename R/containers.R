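#' Particle set
#'
#' A set of puncta ("particles") on a 2-D frame, either ground truth from the
#' synthetic generator or detections from [label_particles()]. Areas are in
#' pixel^2; `n_t` is the total particle count and `c_t` the total particulate
#' area (the sum of all particle areas).
#'
#' @param particles data.frame with columns `x`, `y` (centroids, pixels),
#'   `area` (pixel^2, > 0) and optionally `peak` (peak intensity, a.u.).
#' @param dim integer frame dimensions `c(height, width)` in pixels.
#'
#' @return An object of class `particle_set`: a list with elements
#'   `particles`, `dim`, `n_t` and `c_t`.
#' @export
particle_set <- function(particles, dim) {
  if (is.null(particles) || nrow(particles) == 0L) {
    particles <- data.frame(x = numeric(0), y = numeric(0),
                            area = numeric(0), peak = numeric(0))
  }
  stopifnot(all(c("x", "y", "area") %in% names(particles)),
            length(dim) == 2L, all(dim >= 1))
  if (is.null(particles$peak)) particles$peak <- rep(NA_real_, nrow(particles))
  if (any(particles$area <= 0)) stop("all particle areas must be > 0")
  if (nrow(particles) > 0 &&
      (any(particles$x < 0.5) || any(particles$x > dim[2] + 0.5) ||
       any(particles$y < 0.5) || any(particles$y > dim[1] + 0.5))) {
    stop("particle centroids must lie within the frame")
  }
  structure(list(particles = particles,
                 dim = as.integer(dim),
                 n_t = nrow(particles),
                 c_t = sum(particles$area)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> N_t = %d particles, C_t = %.6g px^2, frame %d x %d\n",
              x$n_t, x$c_t, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Fluorescence image
#'
#' A single-channel 2-D intensity image. Intensities are non-negative and
#' finite, on a 16-bit-like arbitrary-unit scale. The matrix is indexed
#' `[row = y, col = x]`.
#'
#' @param pixels numeric matrix of intensities (>= 0, finite).
#' @param pixel_size pixel size in micrometres per pixel.
#' @param channel channel label.
#' @param meta optional list of acquisition / simulation metadata
#'   (e.g. PSF sigma, background, ground-truth reference).
#'
#' @return Object of class `fluorescence_image`.
#' @export
fluorescence_image <- function(pixels, pixel_size = 0.1, channel = "ch1",
                               meta = list()) {
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("image intensities must be finite and non-negative")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel = channel, meta = meta),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %d x %d px, %.3g um/px, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

# Accept either a fluorescence_image or a bare matrix everywhere.
as_pixels <- function(img) {
  if (inherits(img, "fluorescence_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a fluorescence_image or a numeric matrix")
}

#' Rectangular region of interest
#'
#' @param label one of `"on_cell"`, `"off_cell"`, `"box"`.
#' @param x,y ranges `c(min, max)` of column and row pixel indices (inclusive).
#'
#' @return Object of class `roi`.
#' @export
roi_rect <- function(label = c("on_cell", "off_cell", "box"), x, y) {
  label <- match.arg(label)
  stopifnot(length(x) == 2L, length(y) == 2L, x[1] <= x[2], y[1] <= y[2],
            x[1] >= 1, y[1] >= 1)
  structure(list(label = label, x = as.integer(x), y = as.integer(y)),
            class = "roi")
}

roi_pixels <- function(img, roi) {
  px <- as_pixels(img)
  if (inherits(roi, "roi")) {
    if (roi$x[2] > ncol(px) || roi$y[2] > nrow(px)) {
      stop("ROI extends beyond the image frame")
    }
    px[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], drop = FALSE]
  } else if (is.logical(roi) && is.matrix(roi)) {
    stopifnot(all(dim(roi) == dim(px)))
    if (!any(roi)) stop("ROI is empty")
    px[roi]
  } else stop("ROI must be an roi_rect() or a logical mask matrix")
}

#' Per-cell current-density-voltage record
#'
#' @param cell_id cell identifier.
#' @param group group label (e.g. construct / transfection condition).
#' @param voltage_mV strictly increasing command voltages (mV).
#' @param current_pApF signed current densities (pA/pF); inward negative.
#'
#' @return Object of class `iv_record`.
#' @export
iv_record <- function(cell_id, group, voltage_mV, current_pApF) {
  stopifnot(length(voltage_mV) == length(current_pApF),
            length(voltage_mV) >= 2L)
  if (any(diff(voltage_mV) <= 0)) stop("voltages must be strictly increasing")
  structure(list(cell_id = cell_id, group = group,
                 voltage_mV = as.numeric(voltage_mV),
                 current_pApF = as.numeric(current_pApF)),
            class = "iv_record")
}

#' Current trace
#'
#' Uniformly sampled whole-cell current during a depolarising voltage step.
#'
#' @param time_ms uniformly spaced time axis (ms), starting at 0.
#' @param current current samples (pA/pF).
#' @param rate_kHz sampling rate in kHz.
#'
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(time_ms, current, rate_kHz) {
  stopifnot(length(time_ms) == length(current), length(time_ms) >= 2L)
  dt <- diff(time_ms)
  if (max(abs(dt - dt[1])) > 1e-9) stop("sampling must be uniform")
  structure(list(time_ms = time_ms, current = current, rate_kHz = rate_kHz),
            class = "current_trace")
}

#' Sucrose-gradient densitometry profile
#'
#' Signal in 15 gradient fractions ordered top (light) to bottom (dense),
#' with a designated set of raft (buoyant interface) fractions.
#'
#' @param signal numeric vector of length 15, non-negative.
#' @param raft_fractions 1-based indices of the raft fractions
#'   (default 3:6, the buoyant 5--30% sucrose interface).
#'
#' @return Object of class `gradient_profile`.
#' @export
gradient_profile <- function(signal, raft_fractions = 3:6) {
  stopifnot(length(signal) == 15L)
  if (any(!is.finite(signal)) || any(signal < 0)) {
    stop("fraction signals must be finite and non-negative")
  }
  stopifnot(all(raft_fractions %in% 1:15))
  structure(list(signal = as.numeric(signal),
                 raft_fractions = as.integer(raft_fractions)),
            class = "gradient_profile")
}

#' Protein sequence record
#'
#' @param id sequence identifier.
#' @param seq amino-acid sequence, 1-letter upper-case codes.
#' @param regions optional named list annotating designed regions
#'   (e.g. the intended omega position).
#'
#' @return Object of class `sequence_record`.
#' @export
sequence_record <- function(id, seq, regions = list()) {
  seq <- toupper(seq)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seq)) {
    stop("sequence must use the 20 standard 1-letter amino-acid codes")
  }
  structure(list(id = id, seq = seq, regions = regions),
            class = "sequence_record")
}

as_sequence <- function(x) {
  if (inherits(x, "sequence_record")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a sequence_record or a single character string")
}
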