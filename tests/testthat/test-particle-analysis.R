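test_that("fixed and adaptive thresholding match brute force", {
  const <- matrix(5, 10, 10)
  expect_false(any(threshold_image(const, "fixed", level = 6)))
  expect_true(all(threshold_image(const, "fixed", level = 4)))

  set.seed(11)
  m <- matrix(runif(28 * 23, 0, 100), 28, 23)
  for (w in c(3, 7)) {
    r <- (w - 1) / 2
    bf <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      rows <- pmin(pmax((i - r):(i + r), 1), nrow(m))
      cols <- pmin(pmax((j - r):(j + r), 1), ncol(m))
      bf[i, j] <- mean(m[rows, cols])
    }
    expect_equal(threshold_image(m, "adaptive_local", window = w, offset = 2),
                 m > (bf - 2))
  }
  # one bright blob on a flat background: adaptive mask covers the blob only
  # (negative offset raises the local threshold above flat-background level)
  flat <- matrix(10, 40, 40)
  flat[18:22, 18:22] <- 200
  mask <- threshold_image(flat, "adaptive_local", window = 15, offset = -5)
  expect_true(all(mask[18:22, 18:22]))
  expect_false(any(mask[1:10, 1:10]))
  expect_error(threshold_image(m, "adaptive_local", window = 4), "odd")
})

test_that("connected-component labelling follows the connectivity definition", {
  mk <- matrix(FALSE, 6, 6)
  mk[2, 2] <- TRUE; mk[3, 3] <- TRUE  # touching diagonally
  p8 <- label_particles(mk, connectivity = 8)
  p4 <- label_particles(mk, connectivity = 4)
  expect_equal(p8$n_t, 1L); expect_equal(p8$particles$area, 2)
  expect_equal(p4$n_t, 2L); expect_equal(p4$particles$area, c(1, 1))

  empty <- label_particles(matrix(FALSE, 5, 5))
  expect_equal(empty$n_t, 0L); expect_equal(empty$c_t, 0)

  # idempotence on its own output mask; monotone in min_area
  set.seed(3)
  mk2 <- matrix(runif(60 * 60) > 0.7, 60, 60)
  d1 <- label_particles(mk2, connectivity = 8)
  # the union of labelled component pixels is the input mask itself
  remask <- mk2
  d2 <- label_particles(remask, connectivity = 8)
  expect_equal(d2$n_t, d1$n_t)
  expect_equal(sort(d2$particles$area), sort(d1$particles$area))
  counts <- vapply(c(1, 2, 4, 8),
                   function(a) label_particles(mk2, min_area = a)$n_t,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("size distribution and fractional coverage reproduce the worked example", {
  ps <- worked_example_few_large()
  sd1 <- size_distribution(ps)
  occ <- sd1[sd1$count > 0, ]
  expect_equal(occ$pct, c(80, 20))
  expect_equal(sum(sd1$pct), 100, tolerance = 1e-9)
  fc <- fractional_coverage(ps)
  expect_equal(fc$coverage[fc$coverage > 0], c(0.4, 0.6))
  expect_equal(sum(fc$coverage), 1, tolerance = 1e-12)

  ps2 <- worked_example_many_small()
  sd2 <- size_distribution(ps2)
  expect_equal(round(sd2$pct[sd2$count > 0] / 100, 2), c(0.94, 0.06))
  fc2 <- fractional_coverage(ps2)
  expect_equal(fc2$coverage[fc2$coverage > 0], c(0.6, 0.4))

  single <- particle_set(data.frame(x = 5, y = 5, area = 12), c(20L, 20L))
  expect_equal(sum(fractional_coverage(single)$coverage), 1)
  sds <- size_distribution(single)
  expect_equal(sds$pct[sds$count > 0], 100)
})

test_that("binned statistics agree with brute-force tallies on random sets", {
  ps <- generate_particle_field(300, mean_area = 15, dispersion = 0.5,
                                frame = c(700, 700), seed = 8)
  a <- ps$particles$area
  sd1 <- size_distribution(ps)
  edges <- attr(sd1, "bin_edges")
  brute <- vapply(seq_len(length(edges) - 1L),
                  function(b) sum(a > edges[b] & a <= edges[b + 1]),
                  numeric(1))
  expect_equal(sd1$count, brute)
  expect_equal(sum(sd1$pct), 100, tolerance = 1e-9)

  # coverage from unit bins equals per-particle brute force by size class
  fc <- fractional_coverage(ps)
  brute_cov <- vapply(seq_len(length(edges) - 1L), function(b) {
    sum(a[a > edges[b] & a <= edges[b + 1]]) / ps$c_t
  }, numeric(1))
  expect_equal(fc$coverage, brute_cov, tolerance = 1e-12)
  expect_equal(sum(fc$coverage), 1, tolerance = 1e-12)

  # coarse binning preserves sum(f) = 1 with the mean-area representative
  coarse <- seq(0, ceiling(max(a)) + 5, by = 5)
  fc5 <- fractional_coverage(ps, bin_edges = coarse)
  expect_equal(sum(fc5$coverage), 1, tolerance = 1e-12)
})

test_that("signal-to-background behaves as a ratio of ROI means", {
  img <- matrix(10, 50, 50)
  img[11:30, 11:30] <- 20
  on <- roi_rect("on_cell", x = c(11, 30), y = c(11, 30))
  off <- roi_rect("off_cell", x = c(35, 48), y = c(35, 48))
  sb <- signal_to_background(img, on, off)
  expect_equal(sb$sb, 2)
  expect_equal(sb$sb_minus_1, 1)
  # identical statistics -> (S/B) - 1 = 0
  sb0 <- signal_to_background(img, off, off)
  expect_equal(sb0$sb_minus_1, 0)
  # invariance under positive global scaling
  sb2 <- signal_to_background(3.7 * img, on, off)
  expect_equal(sb2$sb, sb$sb)
  expect_error(signal_to_background(matrix(0, 5, 5),
                                    roi_rect("on_cell", c(1, 2), c(1, 2)),
                                    roi_rect("off_cell", c(3, 4), c(3, 4))),
               "zero")
})

test_that("percent of control matches the printed group means", {
  poc <- percent_of_control(0.10, 0.44)
  expect_equal(poc$percent, 23)
  expect_equal(poc$percent_raw, 100 * 0.10 / 0.44)
  # identical groups -> 100%, p ~ 1
  same <- percent_of_control(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$percent, 100)
  expect_equal(same$comparison$p_value, 1)
  expect_equal(percent_of_control(c(0, 0, 0), c(1, 2))$percent, 0)
  expect_error(percent_of_control(1, 0), "zero")
})

test_that("box scans average across the orthogonal axis", {
  const <- matrix(4.5, 20, 30)
  b <- roi_rect("box", x = c(5, 25), y = c(3, 18))
  expect_true(all(box_scan(const, b, "x")$intensity == 4.5))
  # vertical stripe -> top-hat profile along x
  stripe <- matrix(0, 20, 30); stripe[, 10:15] <- 7
  prof <- box_scan(stripe, roi_rect("box", x = c(1, 30), y = c(1, 20)), "x")
  expect_equal(prof$intensity, ifelse(1:30 %in% 10:15, 7, 0))
  set.seed(5)
  rnd <- matrix(runif(20 * 30), 20, 30)
  expect_equal(box_scan(rnd, b, "x")$intensity, colMeans(rnd[3:18, 5:25]))
  expect_equal(box_scan(rnd, b, "y")$intensity, rowMeans(rnd[3:18, 5:25]))
})

test_that("contour maps quantise monotonically into equal bands", {
  expect_true(all(contour_map(matrix(3, 8, 8), 6) == 0))
  ramp <- matrix(seq(0, 100, length.out = 64), 8, 8)
  cm <- contour_map(ramp, 4)
  expect_equal(sort(unique(as.vector(cm))), 0:3)
  expect_equal(as.vector(table(cm)), rep(16L, 4))
  # brute-force per-pixel band computation
  set.seed(6)
  m <- matrix(runif(100, 0, 1000), 10, 10)
  cm2 <- contour_map(m, 8)
  scaled <- (m - min(m)) / (max(m) - min(m)) * 255
  expect_equal(as.vector(cm2), as.integer(pmin(floor(scaled / 32), 7)))
  expect_true(all(order(as.vector(cm2)) == order(as.vector(cm2)[order(m)])) ||
                all(diff(as.vector(cm2)[order(m)]) >= 0))
})
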