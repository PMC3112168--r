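#' Boltzmann current-density-voltage function
#'
#' `I(V) = g * (V - Vrev) / (1 + exp((V50 - V) / k))`: channel activation
#' (a Boltzmann gate rising with depolarisation, slope factor `k > 0`) times
#' the linear driving force. With `g > 0` and `V < Vrev` the current is
#' negative (inward), matching conventional I-V plots.
#'
#' @param V voltage(s), mV.
#' @param g conductance, nS/pF.
#' @param Vrev reversal potential, mV.
#' @param V50 half-activation voltage, mV.
#' @param k slope factor, mV (> 0).
#'
#' @return Current density, pA/pF.
#' @export
boltzmann_current <- function(V, g, Vrev, V50, k) {
  stopifnot(k != 0)
  g * (V - Vrev) / (1 + exp((V50 - V) / k))
}

# Signed extremum of the Boltzmann curve over a voltage interval.
boltzmann_imax <- function(g, Vrev, V50, k, range = c(-30, 65)) {
  f <- function(V) boltzmann_current(V, g, Vrev, V50, k)
  lo <- stats::optimize(f, range)
  hi <- stats::optimize(f, range, maximum = TRUE)
  cand_v <- c(lo$minimum, hi$maximum, range)
  cand_i <- f(cand_v)
  j <- which.max(abs(cand_i))
  list(imax = cand_i[j], v_at = cand_v[j])
}

#' Preset group parameters emulating an auxiliary-subunit contrast
#'
#' Returns Boltzmann parameters for a pair of groups whose configured
#' contrast is a 4.0-fold enhancement of peak current density |Imax| and a
#' -13 mV shift in V50 in the "plus" group, the canonical effect of
#' co-expressing an alpha2delta subunit with Cav2.2/beta1b channels. The
#' conductances are solved so the |Imax| ratio over the -30..+65 mV protocol
#' is exactly 4.0.
#'
#' @param imax_minus target |Imax| of the reference ("minus") group, pA/pF.
#' @param fold Imax fold enhancement in the "plus" group.
#' @param dv50 V50 shift (mV) in the "plus" group (negative = hyperpolarised).
#'
#' @return Named list of two parameter lists (`minus`, `plus`), each with
#'   `g`, `Vrev`, `V50`, `k` and the implied signed `Imax`.
#' @export
preset_alpha2delta_groups <- function(imax_minus = 20, fold = 4, dv50 = -13) {
  base <- list(Vrev = 50, V50 = 5, k = 6)
  solve_g <- function(target_abs, V50) {
    unit <- abs(boltzmann_imax(1, base$Vrev, V50, base$k)$imax)
    target_abs / unit
  }
  minus <- list(g = solve_g(imax_minus, base$V50), Vrev = base$Vrev,
                V50 = base$V50, k = base$k)
  plus <- list(g = solve_g(imax_minus * fold, base$V50 + dv50),
               Vrev = base$Vrev, V50 = base$V50 + dv50, k = base$k)
  minus$Imax <- boltzmann_imax(minus$g, minus$Vrev, minus$V50, minus$k)$imax
  plus$Imax <- boltzmann_imax(plus$g, plus$Vrev, plus$V50, plus$k)$imax
  list(minus = minus, plus = plus)
}

#' Generate a synthetic I-V dataset
#'
#' Simulates per-cell current-density-voltage families on the standard
#' protocol (-30 to +65 mV in 5 mV steps by default): each cell's currents
#' are the Boltzmann curve at its group's parameters, with optional per-cell
#' parameter jitter (lognormal on g, Gaussian on V50; both off by default)
#' plus additive Gaussian noise.
#'
#' @param group_params named list of groups, each a list with `g`, `Vrev`,
#'   `V50`, `k` (e.g. [preset_alpha2delta_groups()]).
#' @param n_cells cells per group (>= 1).
#' @param noise_sd Gaussian noise SD, pA/pF.
#' @param voltages protocol voltages, mV.
#' @param g_jitter_cv lognormal coefficient of variation of per-cell g.
#' @param v50_jitter_sd Gaussian SD of per-cell V50, mV.
#' @param seed integer seed.
#'
#' @return A tidy data.frame (class `iv_dataset`) with columns `cell_id`,
#'   `group`, `voltage_mV`, `current_pApF`.
#' @export
generate_iv_dataset <- function(group_params, n_cells = 10, noise_sd = 1,
                                voltages = seq(-30, 65, by = 5),
                                g_jitter_cv = 0, v50_jitter_sd = 0,
                                seed = NULL) {
  stopifnot(n_cells >= 1, length(voltages) >= 2)
  if (is.null(names(group_params)) || any(names(group_params) == "")) {
    stop("group_params must be a named list of parameter lists")
  }
  gen <- function() {
    rows <- lapply(names(group_params), function(gname) {
      pp <- group_params[[gname]]
      stopifnot(pp$k != 0)
      lapply(seq_len(n_cells), function(i) {
        g <- if (g_jitter_cv > 0) {
          pp$g * stats::rlnorm(1, -log(1 + g_jitter_cv^2) / 2,
                               sqrt(log(1 + g_jitter_cv^2)))
        } else pp$g
        v50 <- pp$V50 + if (v50_jitter_sd > 0) stats::rnorm(1, 0, v50_jitter_sd) else 0
        curr <- boltzmann_current(voltages, g, pp$Vrev, v50, pp$k)
        if (noise_sd > 0) curr <- curr + stats::rnorm(length(voltages), 0, noise_sd)
        data.frame(cell_id = sprintf("%s_%02d", gname, i), group = gname,
                   voltage_mV = voltages, current_pApF = curr)
      })
    })
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    rownames(out) <- NULL
    class(out) <- c("iv_dataset", "data.frame")
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Split a tidy I-V dataset into per-cell records
#'
#' @param dataset an `iv_dataset` data.frame from [generate_iv_dataset()] or
#'   read from CSV with the same columns.
#' @return Named list of [iv_record()] objects.
#' @export
iv_records <- function(dataset) {
  stopifnot(all(c("cell_id", "group", "voltage_mV", "current_pApF") %in%
                  names(dataset)))
  split_df <- split(dataset, dataset$cell_id)
  recs <- lapply(split_df, function(d) {
    d <- d[order(d$voltage_mV), ]
    iv_record(d$cell_id[1], d$group[1], d$voltage_mV, d$current_pApF)
  })
  recs[unique(dataset$cell_id)]
}

#' Generate a synthetic current trace
#'
#' A depolarising-step current with mono-exponential activation and
#' inactivation envelopes:
#' `I(t) = amplitude * (1 - exp(-t/tau_act)) * exp(-t/tau_inact) + noise`.
#' The noiseless peak occurs at `t = tau_act * log(1 + tau_inact/tau_act)`.
#'
#' @param tau_act activation time constant, ms (> 0).
#' @param tau_inact inactivation time constant, ms (> tau_act).
#' @param amplitude driving amplitude, pA/pF (negative for inward currents).
#' @param duration sweep duration, ms.
#' @param rate_kHz sampling rate, kHz.
#' @param noise_sd Gaussian noise SD, pA/pF.
#' @param seed integer seed.
#'
#' @return A [current_trace()].
#' @export
generate_current_trace <- function(tau_act = 2, tau_inact = 50,
                                   amplitude = -60, duration = 150,
                                   rate_kHz = 10, noise_sd = 0, seed = NULL) {
  if (tau_act <= 0 || tau_inact <= 0) {
    stop("time constants must be positive")
  }
  if (tau_inact <= tau_act) stop("tau_inact must exceed tau_act")
  t <- seq(0, duration, by = 1 / rate_kHz)
  gen <- function() {
    i <- amplitude * (1 - exp(-t / tau_act)) * exp(-t / tau_inact)
    if (noise_sd > 0) i <- i + stats::rnorm(length(t), 0, noise_sd)
    current_trace(t, i, rate_kHz)
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Noiseless peak time of the two-exponential trace envelope
#'
#' Closed form for the argmax of `(1 - exp(-t/tau_act)) * exp(-t/tau_inact)`.
#'
#' @inheritParams generate_current_trace
#' @return Peak time, ms.
#' @export
trace_peak_time <- function(tau_act, tau_inact) {
  stopifnot(tau_act > 0, tau_inact > 0)
  tau_act * log(1 + tau_inact / tau_act)
}
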