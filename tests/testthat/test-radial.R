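test_that("ring averaging agrees with brute-force per-pixel binning", {
  geom <- small_geom(120L)
  set.seed(5)
  img <- matrix(runif(120^2, 0.5, 1.5), 120)
  prof <- radial_ring_average(img, geom, ring_width = 0.5)
  # independent oracle: explicit per-pixel loop binning
  g <- offaxis_grid(geom)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  bins <- split(as.vector(img), floor(as.vector(r) / 0.5))
  expect_equal(prof$mean, vapply(bins, mean, 0), ignore_attr = TRUE)
  expect_equal(prof$count, lengths(bins), ignore_attr = TRUE)
  # bookkeeping identity: count-weighted mean of ring means = image mean
  expect_equal(sum(prof$mean * prof$count) / sum(prof$count), mean(img))
  # constant image: every ring mean equals the constant
  p2 <- radial_ring_average(matrix(3.3, 120, 120), geom)
  expect_true(all(abs(p2$mean - 3.3) < 1e-12))
  # geometry: ring pixel counts grow with radius over the inscribed disk
  full <- prof[!prof$partial, ]
  # counts grow essentially linearly with radius (up to grid quantisation)
  expect_gt(cor(full$r, full$count), 0.98)
  expect_gt(tail(full$count, 1), 10 * full$count[1])
  expect_error(radial_ring_average(img, geom, ring_width = 0), "positive")
})

test_that("ring means converge to the analytic annulus average", {
  # image = r^2: the analytic mean over ring [a, b) is (a^2 + b^2) / 2
  errs <- sapply(c(120L, 360L), function(n) {
    geom <- small_geom(n)
    r <- radius_map(geom)
    prof <- radial_ring_average(r^2, geom, ring_width = 0.5)
    full <- prof[!prof$partial & prof$r > 5, ]
    a <- full$r - 0.25; b <- full$r + 0.25
    max(abs(full$mean / ((a^2 + b^2) / 2) - 1))
  })
  expect_lt(errs[2], errs[1] / 2)   # finer sampling, better agreement
  expect_lt(errs[2], 2e-3)
})

test_that("weighted smoothing fit reproduces noiseless polynomial profiles", {
  geom <- small_geom(238L)
  r <- radius_map(geom)
  br <- 1 + 2e-4 * r^2 - 2e-6 * r^3
  prof <- radial_ring_average(br, geom)
  fn <- smooth_radial_fit(prof)
  rr <- seq(0.5, 19, by = 0.25)
  expect_lt(max(abs(fn(rr) / (1 + 2e-4 * rr^2 - 2e-6 * rr^3) - 1)), 1e-4)
  expect_error(smooth_radial_fit(prof[1:3, ]), "too few rings")
})

test_that("noiseless symmetric-beam pipeline recovers the PSM", {
  sc <- exactness_scenario(beam = beam_model(asym_x = 0, asym_y = 0))
  truth <- scenario_truth(sc)
  acq <- simulate_radial_acquisition(truth, sc$beam, sc$geom,
                                     ideal_noise_sd = 0)
  fit <- fit_psm(acq)
  dev <- percent_deviation_map(fit$psm, truth)
  expect_lt(median(abs(dev[is.finite(dev)])), 0.1)
  # flat panel, symmetric beam: flat PSM (inside the field)
  flat <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0), sc$geom)
  acqf <- simulate_radial_acquisition(flat, sc$beam, sc$geom, ideal_noise_sd = 0)
  fitf <- fit_psm(acqf)
  sel <- radius_map(sc$geom) < 18
  expect_lt(median(abs(fitf$psm$values[sel] - 1)), 2e-4)
  # the dead-column band lands in the PSM
  dcols <- which(colSums(truth$values == 0) > 200)
  expect_true(all(fit$psm$values[, dcols] < 0.1))
})

test_that("beam asymmetry leaks into the radial-method PSM antisymmetrically", {
  sc <- exactness_scenario(beam = beam_model(asym_x = 0.005, asym_y = 0))
  truth <- scenario_truth(sc)
  acq <- simulate_radial_acquisition(truth, sc$beam, sc$geom,
                                     ideal_noise_sd = 0.01, seed = 7L)
  fit <- fit_psm(acq)
  dev <- percent_deviation_map(fit$psm, truth)
  mirr <- dev[, ncol(dev):1]
  sel <- is.finite(dev) & is.finite(mirr) & radius_map(sc$geom) < 18
  expect_gt(cor(dev[sel], -mirr[sel]), 0.9)
  # the leak has the sign and scale of the injected tilt
  g <- offaxis_grid(sc$geom)
  row <- sc$geom$n_rows %/% 2
  expect_equal(dev[row, which.min(abs(g$x - 10))], 0.5, tolerance = 0.15)
})
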