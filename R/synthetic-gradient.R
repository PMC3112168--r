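#' Generate a synthetic sucrose-gradient densitometry profile
#'
#' A two-component profile over 15 fractions (top to bottom): a buoyant raft
#' peak and a dense non-raft peak, each a discretised Gaussian over the
#' fraction index normalised to unit mass over fractions 1..15, mixed
#' `raft_weight : (1 - raft_weight)` and scaled to a configured total signal.
#' With noise off the total is conserved exactly and [raft_fraction()]
#' recovers `raft_weight` up to the small mass of each peak lying outside its
#' designated fraction window (discretisation leakage). Noise is Gaussian
#' with a signal-dependent scale (shot-noise-like densitometry model):
#' `sd_i = noise_sd * sqrt(signal_i / peak)`, i.e. `noise_sd` is the SD at
#' the profile peak and empty fractions stay essentially noise-free.
#'
#' @param raft_weight share of total signal in the raft component, in [0, 1].
#' @param raft_peak raft-peak centre (fraction index, default 4).
#' @param nonraft_peak non-raft-peak centre (fraction index, default 11).
#' @param width Gaussian width of both peaks, in fraction units. The default
#'   (0.7) keeps > 99% of each discretised peak inside its designated
#'   fraction window, emulating the sharply peaked blot profiles.
#' @param noise_sd Gaussian noise SD at the profile peak, signal units
#'   (profiles are clamped at 0).
#' @param total total signal over all 15 fractions (densitometry units).
#' @param raft_fractions designated raft fraction indices (default 3:6).
#' @param seed integer seed.
#'
#' @return A [gradient_profile()].
#' @export
generate_gradient_profile <- function(raft_weight, raft_peak = 4,
                                      nonraft_peak = 11, width = 0.7,
                                      noise_sd = 0, total = 100,
                                      raft_fractions = 3:6, seed = NULL) {
  stopifnot(raft_weight >= 0, raft_weight <= 1,
            raft_peak >= 1, raft_peak <= 15,
            nonraft_peak >= 1, nonraft_peak <= 15, width > 0, total > 0)
  idx <- 1:15
  comp <- function(centre) {
    d <- stats::dnorm(idx, mean = centre, sd = width)
    d / sum(d)
  }
  signal <- total * (raft_weight * comp(raft_peak) +
                     (1 - raft_weight) * comp(nonraft_peak))
  gen <- function() {
    s <- signal
    if (noise_sd > 0) {
      sds <- noise_sd * sqrt(s / max(s))
      s <- pmax(0, s + stats::rnorm(15, 0, sds))
    }
    gradient_profile(s, raft_fractions)
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}
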