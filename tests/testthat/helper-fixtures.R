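# Shared fixtures, built in code.

# The two-size worked example: 4 particles of 10 px^2 and 1 of 60 px^2
# (C_t = 100), and its many-small counterpart (60 x 1 px^2 + 4 x 10 px^2).
worked_example_few_large <- function() {
  particle_set(data.frame(x = rep(50, 5), y = seq(20, 80, length.out = 5),
                          area = c(rep(10, 4), 60)),
               dim = c(100L, 100L))
}

worked_example_many_small <- function() {
  particle_set(data.frame(x = rep(50, 64), y = seq(2, 98, length.out = 64),
                          area = c(rep(1, 60), rep(10, 4))),
               dim = c(100L, 100L))
}

# Standard synthetic imaging conditions used by the round-trip tests:
# well-separated puncta (separation 16 px > 4 * psf_sigma) at SNR ~ 20.
roundtrip_conditions <- function() {
  list(n = 200, mean_area = 20, dispersion = 0.4, frame = c(768L, 768L),
       min_separation = 16, peak = 800, psf_sigma = 1, background = 100,
       read_noise_sd = 5,
       # detection calibration: PSF attenuation of small-disc amplitudes
       # puts the half-max contour at ~0.4 of the nominal peak
       threshold = 100 + 0.4 * 800, min_detect_area = 4)
}

simulate_and_detect <- function(seed, cond = roundtrip_conditions()) {
  field <- generate_particle_field(
    n = cond$n, mean_area = cond$mean_area, dispersion = cond$dispersion,
    frame = cond$frame, min_separation = cond$min_separation,
    peak_intensity = cond$peak, seed = seed)
  img <- render_image(field, psf_sigma = cond$psf_sigma,
                      background = cond$background,
                      noise = "poisson_gaussian",
                      read_noise_sd = cond$read_noise_sd, seed = seed + 10000L)
  det <- label_particles(threshold_image(img, "fixed", level = cond$threshold),
                         connectivity = 8, min_area = cond$min_detect_area,
                         img = img)
  list(field = field, img = img, detected = det)
}
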