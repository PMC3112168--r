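test_that("binomial model curves are normalised to the target C_t", {
  for (tm in c("p4", "6p2q2", "q4")) {
    b <- binomial_size_curve(tm, area_grid = 1:400, Ct = 1e5)
    expect_equal(sum(b$count * b$area), 1e5, tolerance = 1e-6)
    expect_true(all(b$count >= 0))
    expect_equal(sum(b$pct), 100, tolerance = 1e-9)
  }
  # all mass at Ap' for p^4 on a single grid point: N_t = C_t / Ap'
  one <- binomial_size_curve("p4", area_grid = 50, Ct = 1e4)
  expect_equal(attr(one, "n_t"), 1e4 / 50)
  # 6p^2q^2 is symmetric about p = 0.5
  sym <- binomial_size_curve("6p2q2", area_grid = 1:100, Ct = 1e5)
  p <- attr(sym, "p")
  f <- sym$count
  # compare term values at p and 1-p (grid symmetric up to endpoints)
  raw <- 6 * p^2 * (1 - p)^2
  expect_equal(raw, rev(6 * (1 - rev(p))^2 * rev(p)^2), tolerance = 1e-12)
  expect_error(binomial_size_curve("p4", area_grid = c(3, 2, 1)), "increasing")
})

test_that("the three binomial terms give pairwise distinct coverage curves", {
  curves <- lapply(c("p4", "6p2q2", "q4"), function(tm) {
    fractional_coverage(binomial_size_curve(tm, area_grid = 1:400, Ct = 1e5))
  })
  combs <- utils::combn(3, 2)
  for (j in seq_len(ncol(combs))) {
    d <- sum(abs(curves[[combs[1, j]]]$coverage - curves[[combs[2, j]]]$coverage))
    expect_gt(d, 0.1)
  }
})

test_that("stripping rescales areas with the particle count held constant", {
  ps <- generate_particle_field(1e4, mean_area = 10, dispersion = 0.3,
                                frame = c(2500, 2500), seed = 13)
  expect_equal(ps$n_t, 1e4L)
  st <- apply_stripping(ps, 0.5)
  expect_equal(st$n_t, 1e4L)
  expect_equal(st$c_t, ps$c_t / 2)
  expect_equal(st$particles$area, ps$particles$area * 0.5)
  # identity at scale 1
  expect_equal(apply_stripping(ps, 1)$particles$area, ps$particles$area)
  # size-distribution method: area axis scales, counts unchanged
  sd0 <- size_distribution(ps)
  sd5 <- apply_stripping(sd0, 0.5)
  expect_equal(sd5$count, sd0$count)
  expect_equal(sd5$area, sd0$area * 0.5)
  expect_equal(attr(sd5, "c_t"), attr(sd0, "c_t") * 0.5)
  # coverage curve translates on the area axis: same coverage values
  expect_equal(fractional_coverage(sd5)$coverage,
               fractional_coverage(sd0)$coverage, tolerance = 1e-12)
})

test_that("disassembly conserves total area exactly and multiplies N_t", {
  one <- particle_set(data.frame(x = 50, y = 50, area = 10), c(100L, 100L))
  d2 <- apply_disassembly(one, 2)
  expect_equal(d2$n_t, 2L)
  expect_equal(d2$particles$area, c(5, 5))
  expect_equal(d2$c_t, 10)

  ps <- generate_particle_field(200, mean_area = 25, dispersion = 0.5,
                                frame = c(600, 600), seed = 14)
  for (m in c(2, 3, 4)) {
    dm <- apply_disassembly(ps, m)
    expect_identical(dm$c_t, ps$c_t)  # exact conservation
    expect_equal(dm$n_t, m * ps$n_t)
  }
  # uniform set shifts entirely to the Ap/m size class
  unif <- generate_particle_field(50, mean_area = 12, family = "fixed",
                                  frame = c(300, 300), seed = 2)
  d4 <- apply_disassembly(unif, 4)
  expect_true(all(d4$particles$area == 3))
  expect_warning(
    apply_disassembly(particle_set(data.frame(x = 5, y = 5, area = 3),
                                   c(10L, 10L)), 4),
    "below 1 pixel")
})

test_that("divergence comparison flags identity and exact predictions", {
  ps <- generate_particle_field(400, mean_area = 18, dispersion = 0.4,
                                frame = c(800, 800), seed = 15)
  pred <- apply_stripping(ps, 0.5)
  # after == before: distance to before is 0
  r1 <- compare_to_prediction(ps, ps, pred)
  expect_equal(r1$d_before$total, 0)
  expect_equal(r1$verdict, "no_effect")
  # after == stripping prediction: distance to prediction is 0
  r2 <- compare_to_prediction(ps, pred, pred)
  expect_equal(r2$d_predicted$total, 0)
  expect_equal(r2$verdict, "effect")
})

test_that("a null experiment is called no-effect in nearly all replicates", {
  verdicts <- vapply(1:100, function(s) {
    before <- generate_particle_field(500, mean_area = 20, dispersion = 0.4,
                                      frame = c(900, 900), seed = 2 * s)
    after <- generate_particle_field(500, mean_area = 20, dispersion = 0.4,
                                     frame = c(900, 900), seed = 2 * s + 1)
    pred <- apply_stripping(before, 0.5)
    compare_to_prediction(before, after, pred)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "no_effect"), 0.95)
})
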