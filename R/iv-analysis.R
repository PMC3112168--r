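#' Fit the Boltzmann current-density-voltage function
#'
#' Least-squares fit of `I(V) = g * (V - Vrev) / (1 + exp((V50 - V)/k))` to a
#' per-cell I-V record. Initialisation is deterministic and protocol-aware:
#' `Vrev` from the linear zero-crossing of the limb beyond the peak, `V50`
#' from the voltage at half-extremal current, `k = 5` mV, `g` from the
#' driving-force slope at the measured peak. `Imax` is the signed extremum of
#' the fitted curve over the protocol's voltage range.
#'
#' @param rec an [iv_record()], or a list/data.frame with `voltage_mV` and
#'   `current_pApF`.
#'
#' @return List of class `boltzmann_params`: `g`, `Vrev`, `V50`, `k`, `Imax`,
#'   `V_at_Imax`, `residual_norm`, `cov` (parameter covariance), `start`
#'   (initial guesses), plus the cell/group labels if present.
#' @export
fit_boltzmann <- function(rec) {
  V <- rec$voltage_mV; I <- rec$current_pApF
  stopifnot(length(V) == length(I))
  if (length(V) < 6) stop("need at least 6 voltage points to fit")
  if (all(I == 0) || max(abs(I)) < .Machine$double.eps^0.5) {
    stop("degenerate data: currents are indistinguishable from zero")
  }
  i0 <- which.max(abs(I))
  imax_meas <- I[i0]
  # Vrev: first zero crossing after the extremum, linearly interpolated
  vrev0 <- NA_real_
  if (i0 < length(V)) {
    after <- i0:length(V)
    sgn <- sign(I[after])
    cross <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
    if (length(cross) > 0) {
      j <- after[cross[1]]
      vrev0 <- V[j] - I[j] * (V[j + 1] - V[j]) / (I[j + 1] - I[j])
    }
  }
  if (!is.finite(vrev0)) vrev0 <- max(V) + 10
  # V50: first voltage reaching half the extremal magnitude
  half <- which(abs(I) >= abs(imax_meas) / 2)
  v50_0 <- if (length(half) > 0) V[half[1]] else stats::median(V)
  # g: driving-force slope at the measured peak (gate ~ fully open there);
  # fall back to the slope of the final two points
  g0 <- imax_meas / (V[i0] - vrev0)
  if (!is.finite(g0) || g0 <= 0) {
    nv <- length(V)
    g0 <- (I[nv] - I[nv - 1]) / (V[nv] - V[nv - 1])
  }
  if (!is.finite(g0) || g0 == 0) g0 <- max(abs(I)) / max(abs(V - vrev0))
  start <- list(g = g0, Vrev = vrev0, V50 = v50_0, k = 5)
  d <- data.frame(V = V, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ g * (V - Vrev) / (1 + exp((V50 - V) / k)),
                      data = d, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) {
      stop("Boltzmann fit did not converge (start: g=", signif(start$g, 3),
           ", Vrev=", signif(start$Vrev, 3), ", V50=", signif(start$V50, 3),
           ", k=5): ", conditionMessage(e))
    })
  cf <- stats::coef(fit)
  ex <- boltzmann_imax(cf["g"], cf["Vrev"], cf["V50"], cf["k"],
                       range = range(V))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(g = unname(cf["g"]), Vrev = unname(cf["Vrev"]),
                 V50 = unname(cf["V50"]), k = unname(cf["k"]),
                 Imax = ex$imax, V_at_Imax = ex$v_at,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 cov = vc, start = start,
                 cell_id = rec$cell_id, group = rec$group),
            class = "boltzmann_params")
}

#' Measured peak current density
#'
#' The signed extremum of the measured (not fitted) current density over the
#' protocol, with the voltage at which it occurs.
#'
#' @param rec an [iv_record()] or compatible list.
#'
#' @return List with `Imax` (pA/pF, signed) and `V_at_peak` (mV).
#' @export
peak_current_density <- function(rec) {
  V <- rec$voltage_mV; I <- rec$current_pApF
  stopifnot(length(V) >= 1, length(V) == length(I))
  j <- which.max(abs(I))
  list(Imax = I[j], V_at_peak = V[j])
}

#' Fit a single-exponential time constant to one phase of a current trace
#'
#' The trace peak splits the sweep into an activation phase (onset to peak)
#' and an inactivation phase (peak to end). The inactivation phase is fitted
#' with `I(t) = A * exp(-(t - t_peak)/tau)`. For the activation phase the
#' fitted decay is first divided out of the trace (decay compensation), then
#' `I(t) = A * (1 - exp(-t/tau))` is fitted; this removes the bias the
#' concurrent inactivation would otherwise impose on tau_act. The first
#' `blank_ms` of the sweep (capacitive transient) is excluded.
#'
#' @param trace a [current_trace()].
#' @param phase `"activation"` or `"inactivation"`.
#' @param blank_ms initial interval excluded from fitting, ms.
#'
#' @return List of class `kinetic_fit`: `tau` (ms), `amplitude`, `phase`,
#'   `window` (ms), `residual_norm`.
#' @export
fit_single_exponential <- function(trace, phase = c("activation", "inactivation"),
                                   blank_ms = 1) {
  phase <- match.arg(phase)
  t <- trace$time_ms; i <- trace$current
  rng <- range(i)
  if (diff(rng) < .Machine$double.eps^0.5 * max(abs(rng), 1) || all(i == 0)) {
    stop("no identifiable peak: trace is flat")
  }
  # locate the peak on a lightly smoothed trace (robust to noise)
  k <- 5L
  sm <- stats::filter(i, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- i[is.na(sm)]
  ipk <- which.max(abs(sm))
  s <- sign(i[ipk])
  if (s == 0) s <- 1
  y <- i * s  # work on positive-peaked trace
  ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
  fit_decay <- function() {
    win <- which(t >= t[ipk])
    if (length(win) < 4) stop("no identifiable peak: decay window too short")
    d <- data.frame(tt = t[win] - t[ipk], yy = y[win])
    tau0 <- max((t[length(t)] - t[ipk]) / 3, 1e-3)
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau), data = d,
                      start = list(A = max(d$yy), tau = tau0), control = ctl)
  }
  if (phase == "inactivation") {
    fit <- fit_decay()
    cf <- stats::coef(fit)
    out <- list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]) * s,
                phase = phase, window = c(t[ipk], t[length(t)]),
                residual_norm = sqrt(sum(stats::residuals(fit)^2)))
  } else {
    dec <- stats::coef(fit_decay())
    win <- which(t >= blank_ms & t <= t[ipk])
    if (length(win) < 4) stop("no identifiable peak: activation window too short")
    ycorr <- y[win] / exp(-t[win] / dec["tau"])
    d <- data.frame(tt = t[win], yy = ycorr)
    tau0 <- max(t[ipk] / 3, 1e-3)
    fit <- minpack.lm::nlsLM(yy ~ A * (1 - exp(-tt / tau)), data = d,
                             start = list(A = max(d$yy), tau = tau0),
                             control = ctl)
    cf <- stats::coef(fit)
    out <- list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]) * s,
                phase = phase, window = c(blank_ms, t[ipk]),
                residual_norm = sqrt(sum(stats::residuals(fit)^2)))
  }
  if (out$tau <= 0) stop("fit did not converge to a positive time constant")
  structure(out, class = "kinetic_fit")
}

#' Summarise fitted Boltzmann parameters by group
#'
#' Per-group mean +/- SEM of Imax, V50, Vrev, k and g, fold-changes of |Imax|
#' and differences of V50 relative to a reference group, and pairwise
#' Student's t-tests against the reference flagged at the conventional
#' p < 0.05 / 0.01 / 0.001 tiers.
#'
#' @param fits list of [fit_boltzmann()] results (with `group` labels), or a
#'   named list of lists of fits, one element per group.
#' @param reference reference group name; default the first group.
#'
#' @return List of class `group_summary`: `table` (per-group data.frame with
#'   means, SEMs, n, `imax_fold` vs reference, `dV50` vs reference) and
#'   `tests` (data.frame of parameter-wise t-tests with tier flags).
#' @export
summarize_groups <- function(fits, reference = NULL) {
  if (!is.null(names(fits)) && all(vapply(fits, is.list, logical(1))) &&
      !inherits(fits[[1]], "boltzmann_params")) {
    by_group <- fits
  } else {
    groups <- vapply(fits, function(f) as.character(f$group), character(1))
    by_group <- split(fits, groups)[unique(groups)]
  }
  if (any(vapply(by_group, length, integer(1)) < 2)) {
    stop("each group needs at least 2 cells")
  }
  if (is.null(reference)) reference <- names(by_group)[1]
  stopifnot(reference %in% names(by_group))
  params <- c("Imax", "V50", "Vrev", "k", "g")
  get <- function(grp, par) vapply(by_group[[grp]], function(f) f[[par]],
                                   numeric(1))
  tab <- do.call(rbind, lapply(names(by_group), function(gname) {
    row <- data.frame(group = gname, n = length(by_group[[gname]]))
    for (par in params) {
      v <- get(gname, par)
      row[[paste0(par, "_mean")]] <- mean(v)
      row[[paste0(par, "_sem")]] <- stats::sd(v) / sqrt(length(v))
    }
    row
  }))
  ref_imax <- mean(abs(get(reference, "Imax")))
  ref_v50 <- mean(get(reference, "V50"))
  tab$imax_fold <- vapply(tab$group,
                          function(gname) mean(abs(get(gname, "Imax"))) / ref_imax,
                          numeric(1))
  tab$dV50 <- tab$V50_mean - ref_v50
  tests <- do.call(rbind, lapply(setdiff(names(by_group), reference),
                                 function(gname) {
    do.call(rbind, lapply(params, function(par) {
      ht <- stats::t.test(get(gname, par), get(reference, par),
                          var.equal = TRUE)
      data.frame(group = gname, reference = reference, parameter = par,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 flag = p_flags(ht$p.value))
    }))
  }))
  structure(list(table = tab, tests = tests, reference = reference),
            class = "group_summary")
}
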