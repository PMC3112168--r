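test_that("particle field generation honours counts, areas and determinism", {
  empty <- generate_particle_field(0, frame = c(64, 64))
  expect_equal(empty$n_t, 0L)
  expect_equal(empty$c_t, 0)

  fixed <- generate_particle_field(5, mean_area = 10, family = "fixed",
                                   frame = c(128, 128), seed = 3)
  expect_equal(fixed$n_t, 5L)
  expect_equal(fixed$c_t, 50)

  a <- generate_particle_field(500, mean_area = 20, dispersion = 0.4,
                               frame = c(900, 900), seed = 1)
  b <- generate_particle_field(500, mean_area = 20, dispersion = 0.4,
                               frame = c(900, 900), seed = 1)
  expect_identical(a, b)
  expect_equal(a$c_t, sum(a$particles$area))
  expect_true(all(a$particles$area >= 1))
})

test_that("infeasible placement fails with a budget error", {
  expect_error(
    generate_particle_field(50, mean_area = 4, frame = c(40, 40),
                            min_separation = 30, seed = 1),
    "placement infeasible")
})

test_that("rendering preserves integrated intensity and blob structure", {
  empty <- generate_particle_field(0, frame = c(32, 32))
  img0 <- render_image(empty, psf_sigma = 0, background = 7, noise = "none")
  expect_true(all(img0$pixels == 7))

  one <- particle_set(data.frame(x = 16, y = 16, area = 9, peak = 100),
                      c(32L, 32L))
  img1 <- render_image(one, psf_sigma = 0, background = 10, noise = "none")
  # integrated intensity above background = area * peak, exactly
  expect_equal(sum(img1$pixels - 10), 9 * 100)
  expect_equal(sum(img1$pixels > 10), 9)

  img2 <- render_image(one, psf_sigma = 1.2, background = 10, noise = "none")
  expect_equal(sum(img2$pixels - 10), 9 * 100, tolerance = 1e-10)
  # exactly one local maximum above background
  px <- img2$pixels
  peaks <- 0
  for (i in 2:31) for (j in 2:31) {
    nb <- px[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (px[i, j] == max(nb) && px[i, j] > 10 + 1e-9 &&
        sum(nb == max(nb)) == 1) peaks <- peaks + 1
  }
  expect_equal(peaks, 1)
})

test_that("rendered fields round-trip through detection when well separated", {
  rt <- simulate_and_detect(seed = 21)
  expect_equal(rt$detected$n_t, rt$field$n_t)
})

test_that("I-V generator lies exactly on the Boltzmann curve at zero noise", {
  pars <- list(ctrl = list(g = 0.5, Vrev = 48, V50 = 2, k = 6))
  ds <- generate_iv_dataset(pars, n_cells = 1, noise_sd = 0)
  expect_equal(ds$current_pApF,
               boltzmann_current(ds$voltage_mV, 0.5, 48, 2, 6))
  # determinism under a fixed seed
  d1 <- generate_iv_dataset(pars, n_cells = 4, noise_sd = 2, seed = 9)
  d2 <- generate_iv_dataset(pars, n_cells = 4, noise_sd = 2, seed = 9)
  expect_identical(d1, d2)
})

test_that("the preset group pair encodes a 4-fold Imax and -13 mV V50 contrast", {
  pr <- preset_alpha2delta_groups()
  expect_equal(abs(pr$plus$Imax) / abs(pr$minus$Imax), 4.0, tolerance = 1e-9)
  expect_equal(pr$plus$V50 - pr$minus$V50, -13)
  expect_true(pr$minus$Imax < 0)  # inward currents
})

test_that("current traces follow the two-exponential envelope", {
  tr <- generate_current_trace(tau_act = 2, tau_inact = 50, amplitude = -60,
                               duration = 150, rate_kHz = 10, noise_sd = 0)
  t <- tr$time_ms
  expect_equal(tr$current, -60 * (1 - exp(-t / 2)) * exp(-t / 50))
  # noiseless peak at the closed-form time
  tpk <- trace_peak_time(2, 50)
  expect_equal(t[which.max(abs(tr$current))], tpk, tolerance = 0.1)
  # amplitude 0 -> all-zero trace
  z <- generate_current_trace(2, 50, amplitude = 0, noise_sd = 0)
  expect_true(all(z$current == 0))
  # towards tau_inact -> Inf the trace approaches the amplitude
  lim <- generate_current_trace(2, 1e9, amplitude = -60, duration = 150,
                                noise_sd = 0)
  expect_equal(min(lim$current), -60, tolerance = 1e-4)
  expect_error(generate_current_trace(-1, 50), "positive")
  expect_error(generate_current_trace(5, 2), "exceed")
})

test_that("designed sequences satisfy / violate the motif rules by construction", {
  for (s in 1:5) {
    intact <- generate_sequences("intact_gpi", seed = s)
    best <- classify_panel(list(intact))
    expect_equal(best$classification, "anchored")
    expect_equal(best$omega, intact$regions$omega)

    disrupted <- generate_sequences("disrupted_tail", seed = s)
    expect_equal(classify_panel(list(disrupted))$classification, "not_anchored")
  }
  nomotif <- generate_sequences("no_motif", seed = 1)
  # all-lysine tail: no omega candidate passes spacer + tail rules
  cands <- find_omega_candidates(nomotif)
  ok <- vapply(cands, function(om) {
    score_gpi_motif(nomotif, om)$classification == "anchored"
  }, logical(1))
  expect_false(any(ok))
})

test_that("gradient profiles conserve total signal and the raft/non-raft split", {
  for (rw in c(0, 0.2, 0.5, 1)) {
    g <- generate_gradient_profile(rw, total = 100)
    expect_equal(sum(g$signal), 100, tolerance = 1e-9)
  }
  expect_equal(raft_fraction(generate_gradient_profile(0.2))$raft_fraction,
               0.2, tolerance = 0.02)
  expect_equal(raft_fraction(generate_gradient_profile(1))$raft_fraction,
               1, tolerance = 0.02)
  expect_lt(raft_fraction(generate_gradient_profile(0))$raft_fraction, 1e-6)
  g1 <- generate_gradient_profile(0.3, noise_sd = 2, seed = 5)
  g2 <- generate_gradient_profile(0.3, noise_sd = 2, seed = 5)
  expect_identical(g1, g2)
})
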