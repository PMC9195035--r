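test_that("ground-truth PSM reflects the defect model", {
  geom <- small_geom(238L)
  # no defects at all: a flat panel
  flat <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0), geom)
  expect_equal(flat$values, matrix(1, 238, 238))
  # static pixel spread: empirical SD close to nominal at n ~ 56000
  for (sd_seed in c(2L, 9L)) {
    tex <- generate_ground_truth_psm(
      panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0.02,
                         seed = sd_seed), geom)
    expect_gt(sd(tex$values), 0.018)
    expect_lt(sd(tex$values), 0.022)
  }
  # dead columns zeroed and masked, everything else valid
  dc <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0,
                       dead_columns = 30L), geom)
  expect_true(all(dc$values[, 30] == 0))
  expect_true(all(!dc$valid_mask[, 30]))
  expect_true(all(dc$valid_mask[, -30]))
  # frozen per seed
  again <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0.02,
                       seed = 2L), geom)
  tex <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0.02,
                       seed = 2L), geom)
  expect_identical(tex$values, again$values)
})

test_that("beam fluence has the configured flattened-beam structure", {
  bm <- beam_model(asym_x = 0, asym_y = 0)
  expect_equal(beam_fluence(bm, 0, 0), 1)
  # mirror symmetry of the symmetric model
  xs <- c(3.2, 7.9, 14.5); ys <- c(-2, 5, 11)
  expect_equal(beam_fluence(bm, xs, ys), beam_fluence(bm, -xs, ys))
  expect_equal(beam_fluence(bm, xs, ys), beam_fluence(bm, xs, -ys))
  # horns: response further off-axis exceeds the shoulder value
  expect_gt(beam_fluence(bm, 15, 0), beam_fluence(bm, 5, 0))
  # asymmetry tilts one side up
  ba <- beam_model(asym_x = 0.005, asym_y = 0)
  expect_gt(beam_fluence(ba, 10, 0), beam_fluence(ba, -10, 0))
  # field edge falls off outside the collimated field
  expect_lt(beam_fluence(bm, 20.5, 0) / beam_fluence(bm, 19, 0), 0.5)
})

test_that("raw-image rendering composes psm, beam, MU and inverse square", {
  geom <- small_geom(32L)
  bm <- bicubic_beam(0)
  ones <- matrix(1, 32, 32)
  img <- render_raw_image(ones, bm, geom, mu = 50)
  expect_equal(img$pixels, 50 * beam_response_truth(bm, geom)$values)
  # dead column in the psm propagates to the raw image
  p <- ones; p[, 5] <- 0
  expect_true(all(render_raw_image(p, bm, geom, mu = 10)$pixels[, 5] == 0))
  # bitwise deterministic per seed
  ns <- acquisition_noise(readout_noise_sd = 0.01, output_fluctuation_sd = 0.01)
  a <- render_raw_image(ones, bm, geom, mu = 10, noise = ns, seed = 7)
  b <- render_raw_image(ones, bm, geom, mu = 10, noise = ns, seed = 7)
  expect_identical(a$pixels, b$pixels)
  # inverse square and magnification: doubling SID quarters the central
  # signal (uniform beam, so no profile confound) and halves the off-axis
  # coordinate of a given pixel
  bu <- beam_model(radial_coeffs = 1, horn_amplitude = 0, asym_x = 0,
                   asym_y = 0, shadow_depth = 0)
  near_u <- render_raw_image(ones, bu, geom, mu = 50)
  g2 <- geom; g2$sid <- 200
  far <- render_raw_image(ones, bu, g2, mu = 50)
  ctr <- function(m) mean(m[16:17, 16:17])
  expect_equal(ctr(far$pixels) / ctr(near_u$pixels), 0.25, tolerance = 1e-9)
  expect_equal(offaxis_grid(g2)$x, offaxis_grid(geom)$x / 2)
  expect_error(render_raw_image(ones, bm, geom, mu = -1), "non-negative")
})

test_that("output fluctuation is a single global scale per irradiation", {
  geom <- small_geom(32L)
  bm <- beam_model()
  set.seed(4)
  p <- matrix(runif(32^2, 0.9, 1.1), 32)
  ns <- acquisition_noise(output_fluctuation_sd = 0.01)
  a <- render_raw_image(p, bm, geom, noise = ns, seed = 1)
  b <- render_raw_image(p, bm, geom, noise = ns, seed = 2)
  ratio <- a$pixels / b$pixels
  expect_lt(diff(range(ratio)), 1e-12)
  expect_gt(abs(ratio[1, 1] - 1), 1e-5)
})

test_that("ABDF sequences interleave signal, offset, lag and residual", {
  geom <- small_geom(16L)
  bm <- bicubic_beam(0)
  ones <- matrix(1, 16, 16)
  # lag 0: every dark frame is the flat offset
  seq0 <- simulate_abdf_sequence(ones, bm, geom, n_pairs = 3, mu_per_frame = 2,
                                 noise = acquisition_noise(dark_offset = 10))
  for (p in seq0) expect_equal(p$dark$pixels, matrix(10, 16, 16))
  # lag: the first dark frame carries a fraction of the first beam frame
  seql <- simulate_abdf_sequence(ones, bm, geom, n_pairs = 2, mu_per_frame = 2,
                                 noise = acquisition_noise(dark_offset = 10,
                                                           lag_fraction = 0.05))
  expect_equal(seql[[1]]$dark$pixels,
               10 + 0.05 * seql[[1]]$beam$pixels, tolerance = 1e-12)
  # a carried-in residual decays: early pairs contaminated, late pairs clean
  resid <- 5 * matrix(1, 16, 16)
  seqr <- simulate_abdf_sequence(ones, bm, geom, n_pairs = 50, mu_per_frame = 2,
                                 initial_residual = resid)
  net <- function(p) p$beam$pixels - p$dark$pixels
  truthsig <- 2 * beam_response_truth(bm, geom)$values
  err_first <- max(abs(net(seqr[[1]]) - truthsig))
  err_last <- max(abs(net(seqr[[50]]) - truthsig))
  expect_gt(err_first, 0.1)
  expect_lt(err_last, 1e-3)
  expect_error(simulate_abdf_sequence(ones, bm, geom, n_pairs = 0), "at least 1")
})

test_that("noiseless render decomposes exactly against the simulator truth", {
  geom <- small_geom(64L)
  bm <- beam_model()
  truth <- generate_ground_truth_psm(
    panel_defect_model(pixel_noise_sd = 0.02, seed = 3L), geom)
  img <- render_raw_image(truth, bm, geom, mu = 100)
  rec <- decompose_image(img, beam_response_truth(bm, geom))
  expect_lt(max(abs(rec$values - truth$values)), 1e-10)
})
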