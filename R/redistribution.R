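#' Binomial-family model size distribution at fixed total particulate area
#'
#' Model curves for punctum populations built from a binomial family: the
#' expected particle count at area `a` is proportional to the chosen term
#' evaluated at `p = a / Ap'` (the area axis mapped linearly onto
#' `p` in (0, 1], `Ap'` = largest area on the grid), with `q = 1 - p`. The
#' overall count scale `N_t` is set so the total particulate area matches a
#' target: `sum(Np_i * Ap_i) = C_t`. Curves are expected (continuous) counts
#' by default; `sample = TRUE` draws seeded Poisson counts around them.
#'
#' @param term `"p4"`, `"6p2q2"` or `"q4"`.
#' @param area_grid positive, strictly increasing area axis (pixel^2).
#' @param Ct target total particulate area (pixel^2, > 0).
#' @param sample draw Poisson counts instead of expected counts.
#' @param seed integer seed (used when `sample = TRUE`).
#'
#' @return A `size_distribution` data.frame (columns `area`, `count`, `pct`)
#'   with attributes `n_t`, `c_t`, `ap_max`, `term`, `p`.
#' @export
binomial_size_curve <- function(term = c("p4", "6p2q2", "q4"),
                                area_grid = 1:400, Ct = 1e5,
                                sample = FALSE, seed = NULL) {
  term <- match.arg(term)
  stopifnot(Ct > 0, length(area_grid) >= 1, all(area_grid > 0))
  if (length(area_grid) > 1 && any(diff(area_grid) <= 0)) {
    stop("area grid must be strictly increasing")
  }
  p <- area_grid / max(area_grid)
  q <- 1 - p
  f <- switch(term, p4 = p^4, `6p2q2` = 6 * p^2 * q^2, q4 = q^4)
  denom <- sum(f * area_grid)
  if (denom <= 0) stop("degenerate area axis: model term is zero everywhere")
  np <- f * Ct / denom
  if (sample) {
    draw <- function() stats::rpois(length(np), lambda = np)
    np <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
    # preserve the C_t normalisation in expectation; recompute realised totals
  }
  n_t <- sum(np)
  out <- data.frame(area = area_grid, count = np,
                    pct = if (n_t > 0) 100 * np / n_t else 0 * np)
  structure(out, class = c("size_distribution", "data.frame"),
            n_t = n_t, c_t = sum(np * area_grid), ap_max = max(area_grid),
            term = term, p = p)
}

#' Apply a "stripping" transformation
#'
#' Stripping models a uniform loss of material from every punctum: each
#' particle area is multiplied by `scale` while the particle count is held
#' constant, so `C_t` scales by `scale` and the size-distribution shape is
#' preserved under area rescaling.
#'
#' @param x a [particle_set()] or `size_distribution`.
#' @param scale area scale factor in (0, 1].
#' @param ... unused.
#'
#' @return Transformed object of the same class.
#' @export
apply_stripping <- function(x, scale = 0.5, ...) UseMethod("apply_stripping")

#' @rdname apply_stripping
#' @export
apply_stripping.particle_set <- function(x, scale = 0.5, ...) {
  stopifnot(scale > 0, scale <= 1)
  p <- x$particles
  p$area <- p$area * scale
  particle_set(p, x$dim)
}

#' @rdname apply_stripping
#' @export
apply_stripping.size_distribution <- function(x, scale = 0.5, ...) {
  stopifnot(scale > 0, scale <= 1)
  out <- data.frame(area = x$area * scale, count = x$count, pct = x$pct)
  structure(out, class = class(x),
            n_t = attr(x, "n_t"), c_t = attr(x, "c_t") * scale,
            ap_max = attr(x, "ap_max") * scale,
            bin_edges = attr(x, "bin_edges") * scale)
}

#' Apply a "disassembly" transformation
#'
#' Disassembly models fragmentation of each punctum into `m` smaller puncta:
#' every particle is replaced by `m` fragments whose areas sum exactly to the
#' parent area (each `area / m`, the last absorbing the floating-point
#' remainder), placed tangentially around the parent centroid. `C_t` is
#' conserved exactly and `N_t` becomes `m * N_t`. Fragments smaller than one
#' pixel trigger a warning (sub-resolution puncta), not an error.
#'
#' @param ps a [particle_set()].
#' @param m integer number of fragments per particle (>= 2).
#'
#' @return A [particle_set()].
#' @export
apply_disassembly <- function(ps, m) {
  stopifnot(inherits(ps, "particle_set"), m == round(m), m >= 2)
  if (ps$n_t == 0L) return(ps)
  p <- ps$particles
  frag_area <- rep(p$area / m, each = m)
  # exact conservation: last fragment takes the remainder
  last <- seq_len(ps$n_t) * m
  frag_area[last] <- p$area - (m - 1) * (p$area / m)
  if (any(frag_area < 1)) {
    warning("some fragment areas fall below 1 pixel^2 (sub-resolution)")
  }
  r_parent <- sqrt(rep(p$area, each = m) / pi)
  ang <- rep(2 * pi * (seq_len(m) - 1) / m, times = ps$n_t)
  fx <- rep(p$x, each = m) + r_parent * cos(ang)
  fy <- rep(p$y, each = m) + r_parent * sin(ang)
  fx <- pmin(pmax(fx, 1), ps$dim[2])
  fy <- pmin(pmax(fy, 1), ps$dim[1])
  particle_set(data.frame(x = fx, y = fy, area = frag_area,
                          peak = rep(p$peak, each = m)), ps$dim)
}

# Coerce particle sets / size distributions onto one common bin grid and
# return normalised count and coverage vectors.
dist_on_grid <- function(x, bin_edges) {
  if (inherits(x, "particle_set")) {
    x <- size_distribution(x, bin_edges)
  } else if (inherits(x, "size_distribution")) {
    # rebin model / observed curves by assigning grid areas to bins
    bin <- findInterval(x$area, bin_edges, rightmost.closed = TRUE)
    if (any(bin < 1 | bin > length(bin_edges) - 1)) {
      stop("incompatible grids: areas fall outside the common bin edges")
    }
    nb <- length(bin_edges) - 1L
    count <- vapply(seq_len(nb),
                    function(b) sum(x$count[bin == b]), numeric(1))
    area_w <- vapply(seq_len(nb), function(b) {
      cb <- x$count[bin == b]
      if (sum(cb) > 0) sum(x$area[bin == b] * cb) / sum(cb)
      else (bin_edges[b] + bin_edges[b + 1]) / 2
    }, numeric(1))
    x <- structure(data.frame(area = area_w, count = count,
                              pct = 100 * count / sum(count)),
                   class = c("size_distribution", "data.frame"),
                   n_t = sum(count), c_t = sum(count * area_w),
                   ap_max = max(x$area), bin_edges = bin_edges)
  } else stop("expected a particle_set or size_distribution")
  list(counts = x$count / sum(x$count),
       coverage = fractional_coverage(x)$coverage)
}

#' Compare an observed distribution with before/prediction alternatives
#'
#' Quantifies, on a common area grid, how far an observed post-treatment
#' size distribution lies from (i) the pre-treatment distribution and
#' (ii) a model prediction of the treatment effect (e.g. stripping at 50%),
#' using the L1 distance on normalised counts and on fractional coverage
#' (mean of the two). The verdict is `"no_effect"` when the observation is
#' at least as close to the pre-treatment distribution as to the prediction,
#' `"effect"` otherwise.
#'
#' @param observed_before,observed_after,predicted_after [particle_set()]s or
#'   `size_distribution`s.
#' @param bin_edges common area bin edges; default unit bins spanning all
#'   three inputs.
#'
#' @return List of class `divergence_report`: `d_before`, `d_predicted`
#'   (each with `counts`, `coverage`, `total`), and `verdict`.
#' @export
compare_to_prediction <- function(observed_before, observed_after,
                                  predicted_after, bin_edges = NULL) {
  max_area <- function(x) {
    if (inherits(x, "particle_set")) max(x$particles$area) else max(x$area)
  }
  if (is.null(bin_edges)) {
    top <- max(vapply(list(observed_before, observed_after, predicted_after),
                      max_area, numeric(1)))
    bin_edges <- seq(0, ceiling(top) + 1, by = 1)
  }
  a <- dist_on_grid(observed_after, bin_edges)
  b <- dist_on_grid(observed_before, bin_edges)
  p <- dist_on_grid(predicted_after, bin_edges)
  l1 <- function(u, v) sum(abs(u - v))
  d <- function(ref) {
    dc <- l1(a$counts, ref$counts)
    dv <- l1(a$coverage, ref$coverage)
    list(counts = dc, coverage = dv, total = (dc + dv) / 2)
  }
  d_before <- d(b); d_pred <- d(p)
  structure(list(d_before = d_before, d_predicted = d_pred,
                 verdict = if (d_before$total <= d_pred$total) "no_effect"
                           else "effect",
                 bin_edges = bin_edges),
            class = "divergence_report")
}
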