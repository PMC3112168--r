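# Local mean over a square window via an integral image with
# replicate-padded edges.
local_mean <- function(mat, window) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  r <- (window - 1L) / 2L
  h <- nrow(mat); w <- ncol(mat)
  pad <- mat[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
  cs <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- rbind(0, cbind(0, t(cs)))                  # (h+2r+1) x (w+2r+1)
  i1 <- 1:h; i2 <- i1 + window
  j1 <- 1:w; j2 <- j1 + window
  box <- cs[i2, j2] - cs[i1, j2] - cs[i2, j1] + cs[i1, j1]
  box / window^2
}

#' Threshold an image
#'
#' Fixed global or adaptive local-mean thresholding. The adaptive method
#' marks a pixel as foreground when its intensity exceeds the mean over a
#' square window centred on it, minus `offset` (the classical ImageJ-style
#' adaptive mean threshold).
#'
#' @param img a [fluorescence_image()] or numeric matrix.
#' @param method `"fixed"` or `"adaptive_local"`.
#' @param level global threshold for `"fixed"` (foreground = intensity > level).
#' @param window odd window size (>= 3) for `"adaptive_local"`.
#' @param offset intensity subtracted from the local mean before comparison.
#'
#' @return A logical matrix mask (TRUE = foreground).
#' @export
threshold_image <- function(img, method = c("fixed", "adaptive_local"),
                            level = NULL, window = 15, offset = 0) {
  method <- match.arg(method)
  px <- as_pixels(img)
  if (method == "fixed") {
    if (is.null(level)) stop("fixed thresholding needs a level")
    px > level
  } else {
    px > (local_mean(px, window) - offset)
  }
}

#' Label connected particles in a binary mask
#'
#' Connected-component labelling (4- or 8-connectivity) of a thresholded
#' image; each component of at least `min_area` pixels becomes one particle
#' with `area` = pixel count and centroid = mean pixel position. If the
#' source image is supplied, each particle also records its peak intensity.
#'
#' @param mask logical matrix from [threshold_image()].
#' @param connectivity 4 or 8 (default 8, common particle-analysis practice).
#' @param min_area minimum component area in pixel^2.
#' @param img optional image (matrix or [fluorescence_image()]) used to
#'   record per-particle peak intensities.
#'
#' @return A [particle_set()].
#' @export
label_particles <- function(mask, connectivity = 8, min_area = 1, img = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(particle_set(NULL, c(h, w)))
  rank <- integer(h * w)
  rank[fg] <- seq_along(fg)
  edge_pairs <- function(a_rows, a_cols, offset) {
    # adjacency between pixel (r, c) and (r, c) + offset in column-major index
    sub <- mask[a_rows, a_cols, drop = FALSE]
    idx <- which(sub)
    if (length(idx) == 0L) return(NULL)
    rr <- ((idx - 1L) %% length(a_rows)) + a_rows[1]
    cc <- ((idx - 1L) %/% length(a_rows)) + a_cols[1]
    i1 <- (cc - 1L) * h + rr
    i2 <- i1 + offset
    keep <- mask[i2]
    cbind(rank[i1[keep]], rank[i2[keep]])
  }
  edges <- list(
    if (h > 1) edge_pairs(1:(h - 1), 1:w, 1L),          # down
    if (w > 1) edge_pairs(1:h, 1:(w - 1), h)            # right
  )
  if (connectivity == 8 && h > 1 && w > 1) {
    edges <- c(edges, list(
      edge_pairs(1:(h - 1), 1:(w - 1), h + 1L),         # down-right
      edge_pairs(2:h, 1:(w - 1), h - 1L)                # up-right
    ))
  }
  edges <- do.call(rbind, Filter(Negate(is.null), edges))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  area <- tabulate(memb)
  cx <- tapply(cols, memb, mean)
  cy <- tapply(rows, memb, mean)
  peak <- if (!is.null(img)) {
    px <- as_pixels(img)
    stopifnot(all(dim(px) == dim(mask)))
    as.numeric(tapply(px[fg], memb, max))
  } else rep(NA_real_, length(area))
  keep <- area >= min_area
  particle_set(data.frame(x = as.numeric(cx)[keep], y = as.numeric(cy)[keep],
                          area = as.numeric(area)[keep], peak = peak[keep]),
               c(h, w))
}

# Default bin edges: unit-width bins centred on integer areas up to the
# largest particle (Ap').
default_bin_edges <- function(areas) {
  seq(0.5, ceiling(max(areas)) + 0.5, by = 1)
}

#' Particle size distribution
#'
#' Bins particle areas and expresses the count in each bin, `Np_i`, as a
#' percentage of the total particle count `N_t` (so overlays from images with
#' different absolute counts are comparable). The bin's representative area
#' is the mean area of its member particles (equal to the bin midpoint for
#' unit bins; midpoint is used for empty bins).
#'
#' @param ps a [particle_set()] (non-empty).
#' @param bin_edges area bin edges covering all particle areas; default
#'   unit-width bins up to the largest particle.
#'
#' @return A data.frame of class `size_distribution` with columns `area`
#'   (representative area), `count` (`Np_i`) and `pct` (`100 * Np_i / N_t`),
#'   and attributes `n_t`, `c_t`, `ap_max`, `bin_edges`.
#' @export
size_distribution <- function(ps, bin_edges = NULL) {
  stopifnot(inherits(ps, "particle_set"))
  if (ps$n_t == 0L) stop("empty particle set")
  a <- ps$particles$area
  if (is.null(bin_edges)) bin_edges <- default_bin_edges(a)
  if (min(a) < bin_edges[1] || max(a) > bin_edges[length(bin_edges)]) {
    stop("bin edges must cover the full range of particle areas")
  }
  bin <- findInterval(a, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  count <- tabulate(bin, nbins = nb)
  mid <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
  rep_area <- mid
  occ <- sort(unique(bin))
  rep_area[occ] <- as.numeric(tapply(a, bin, mean))
  out <- data.frame(area = rep_area, count = count,
                    pct = 100 * count / ps$n_t)
  structure(out, class = c("size_distribution", "data.frame"),
            n_t = ps$n_t, c_t = ps$c_t, ap_max = max(a), bin_edges = bin_edges)
}

#' Fractional coverage curve
#'
#' The share of total particulate area `C_t` contributed by each size class:
#' `f_i = Np_i * Ap_i / C_t`, with `Ap_i` the bin's representative area
#' (mean member area, so `sum(f_i) = 1` at machine precision for any
#' binning). Discriminates whether coverage comes from many small particles
#' or few large ones.
#'
#' @param x a [particle_set()] or a [size_distribution()] (e.g. a model curve
#'   from [binomial_size_curve()]).
#' @param bin_edges area bin edges (particle-set method only).
#' @param ... unused.
#'
#' @return A data.frame of class `fractional_coverage` with columns `area`
#'   and `coverage`, and attributes `c_t`, `n_t`.
#' @export
fractional_coverage <- function(x, ...) UseMethod("fractional_coverage")

#' @rdname fractional_coverage
#' @export
fractional_coverage.particle_set <- function(x, bin_edges = NULL, ...) {
  if (x$c_t <= 0) stop("total particulate area must be positive")
  sd <- size_distribution(x, bin_edges)
  fractional_coverage(sd)
}

#' @rdname fractional_coverage
#' @export
fractional_coverage.size_distribution <- function(x, ...) {
  c_t <- attr(x, "c_t")
  if (is.null(c_t) || c_t <= 0) stop("total particulate area must be positive")
  out <- data.frame(area = x$area, coverage = x$count * x$area / c_t)
  structure(out, class = c("fractional_coverage", "data.frame"),
            c_t = c_t, n_t = attr(x, "n_t"))
}

#' Signal-to-background ratio of a raw image
#'
#' `S/B` is the mean intensity over an on-cell ROI divided by the mean over
#' an off-cell (background) ROI of the same raw, non-background-subtracted
#' image; `(S/B) - 1` is the background-referenced surface-labelling
#' intensity used for group comparisons.
#'
#' @param img a raw [fluorescence_image()] or matrix.
#' @param on on-cell ROI ([roi_rect()] or logical mask).
#' @param off off-cell ROI.
#' @param statistic `"mean"` (default) or `"median"` per-ROI summary.
#'
#' @return List of class `sb_result` with `sb`, `sb_minus_1`, `on_mean`,
#'   `off_mean`, `statistic`.
#' @export
signal_to_background <- function(img, on, off, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "mean") mean else stats::median
  on_v <- f(roi_pixels(img, on))
  off_v <- f(roi_pixels(img, off))
  if (off_v == 0) stop("off-cell background is zero; S/B undefined")
  structure(list(sb = on_v / off_v, sb_minus_1 = on_v / off_v - 1,
                 on_mean = on_v, off_mean = off_v, statistic = statistic),
            class = "sb_result")
}

#' Percent of control
#'
#' Summarises a treatment effect on background-referenced intensities as
#' `100 * mean(treated) / mean(control)`, reported rounded to the nearest
#' integer percent (full precision is also returned), with a two-sample
#' t-test when both groups have n >= 2.
#'
#' @param treated numeric vector of `(S/B) - 1` values in the treated group.
#' @param control numeric vector of `(S/B) - 1` values in the control group.
#'
#' @return List of class `percent_of_control` with `percent` (integer-rounded),
#'   `percent_raw`, group means/SEMs/n, and `comparison` (a
#'   [compare_groups()] result, or NULL if either n < 2).
#' @export
percent_of_control <- function(treated, control) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  m_t <- mean(treated); m_c <- mean(control)
  if (m_c == 0) stop("control mean is zero; percent of control undefined")
  cmp <- if (length(treated) >= 2 && length(control) >= 2) {
    compare_groups(list(treated = treated, control = control), test = "t_test")
  } else NULL
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(percent = round(100 * m_t / m_c),
                 percent_raw = 100 * m_t / m_c,
                 treated_mean = m_t, treated_sem = sem(treated),
                 n_treated = length(treated),
                 control_mean = m_c, control_sem = sem(control),
                 n_control = length(control),
                 comparison = cmp),
            class = "percent_of_control")
}

#' Box scan
#'
#' Averages intensity across one axis of a rectangular ROI to give a 1-D
#' profile along the other, suppressing the noise of single line scans.
#'
#' @param img a [fluorescence_image()] or matrix.
#' @param box a [roi_rect()] within the frame.
#' @param axis `"x"` (profile along columns, averaging rows; default) or
#'   `"y"`.
#'
#' @return data.frame with `position` (pixel index along the chosen axis)
#'   and `intensity`.
#' @export
box_scan <- function(img, box, axis = c("x", "y")) {
  axis <- match.arg(axis)
  sub <- roi_pixels(img, box)
  if (!is.matrix(sub)) stop("box scans need a rectangular ROI")
  if (axis == "x") {
    data.frame(position = box$x[1]:box$x[2], intensity = colMeans(sub))
  } else {
    data.frame(position = box$y[1]:box$y[2], intensity = rowMeans(sub))
  }
}

#' Contour (quantised level) map
#'
#' Rescales an image to the 0-255 display range and quantises it into
#' `n_levels` equal intensity bands, the representation used for contour
#' maps of punctate labelling. Band index is monotone in input intensity.
#' A constant image maps to a single band (band 0).
#'
#' @param img a [fluorescence_image()] or matrix.
#' @param n_levels number of bands (>= 2).
#'
#' @return Integer matrix of band indices in `0:(n_levels - 1)`, with
#'   attribute `scale` giving the 0-255 rescaling parameters.
#' @export
contour_map <- function(img, n_levels = 8) {
  stopifnot(n_levels >= 2)
  px <- as_pixels(img)
  rng <- range(px)
  if (rng[1] == rng[2]) {
    out <- matrix(0L, nrow(px), ncol(px))
  } else {
    scaled <- (px - rng[1]) / (rng[2] - rng[1]) * 255
    out <- pmin(floor(scaled / (256 / n_levels)), n_levels - 1L)
    storage.mode(out) <- "integer"
  }
  attr(out, "scale") <- list(min = rng[1], max = rng[2], levels = n_levels)
  out
}
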