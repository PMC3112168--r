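#' Raft signal fraction of a gradient profile
#'
#' The share of total densitometry signal lying in the designated raft
#' (buoyant-interface) fractions: `sum(signal[raft]) / sum(signal)`.
#' Invariant under global positive rescaling of the profile.
#'
#' @param profile a [gradient_profile()].
#'
#' @return List of class `raft_report`: `raft_fraction`, `normalized`
#'   (per-fraction profile summing to 1), `raft_fractions`.
#' @export
raft_fraction <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  total <- sum(profile$signal)
  if (total <= 0) stop("profile total signal is zero")
  structure(list(raft_fraction = sum(profile$signal[profile$raft_fractions]) / total,
                 normalized = profile$signal / total,
                 raft_fractions = profile$raft_fractions),
            class = "raft_report")
}

#' Detect a raft-to-non-raft shift between paired profiles
#'
#' Declares a shift when the raft signal fraction drops by at least
#' `min_drop` relative to its pre-treatment value (default 0.5, i.e. at
#' least half the raft-resident signal moved to denser fractions).
#'
#' @param before,after [gradient_profile()]s (same raft fraction set).
#' @param min_drop minimum relative drop in raft fraction to call a shift.
#'
#' @return List of class `shift_verdict`: `verdict` (`"shifted"` /
#'   `"unchanged"`), `raft_before`, `raft_after`, `relative_drop`.
#' @export
detect_shift <- function(before, after, min_drop = 0.5) {
  rb <- raft_fraction(before)$raft_fraction
  ra <- raft_fraction(after)$raft_fraction
  drop <- if (rb > 0) (rb - ra) / rb else 0
  structure(list(verdict = if (drop >= min_drop) "shifted" else "unchanged",
                 raft_before = rb, raft_after = ra, relative_drop = drop),
            class = "shift_verdict")
}
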