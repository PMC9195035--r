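test_that("offset plan enumerates the sampling grid", {
  plan <- cmn_plan()
  expect_equal(nrow(plan$points), 42L)          # 7 lateral x 6 longitudinal
  expect_equal(length(plan$x), 7L)
  expect_equal(length(plan$y), 6L)
  expect_equal(range(plan$points$x), c(-15, 15))
  expect_equal(range(plan$points$y), c(-15, 10))
  # shifting the panel by -p puts the beam axis on panel point p
  expect_equal(plan$points$shift_x, -plan$points$x)
  expect_equal(nrow(cmn_plan(c(-5, 5), c(-5, 5), step = 5)$points), 9L)
  expect_error(cmn_plan(step = 0), "positive")
  expect_error(cmn_plan(c(-14, 15), c(-15, 10), step = 5), "multiples")
  # ROI must stay clear of the small-field penumbra
  expect_error(cmn_plan(roi_halfwidth = 2.0, field = 5), "penumbra")
})

test_that("relative sensitivities cancel the beam exactly", {
  sc <- exactness_scenario()
  truth <- exact_truth()
  plan <- cmn_plan()
  a1 <- simulate_cmn_acquisition(truth, sc$beam, sc$geom, plan)
  s1 <- relative_sensitivity_at_points(a1, plan)
  # a flat panel gives unit ratios
  flat <- generate_ground_truth_psm(
    panel_defect_model(smooth_gain_amplitude = 0, pixel_noise_sd = 0), sc$geom)
  af <- simulate_cmn_acquisition(flat, sc$beam, sc$geom, plan)
  # exact in the continuum; the residual is the sub-pixel discretization of
  # the ROI integral (different grid alignment at each sample point)
  expect_lt(max(abs(relative_sensitivity_at_points(af, plan) - 1)), 2e-4)
  # beam independence: a very different beam leaves the ratios unchanged
  b2 <- beam_model(radial_coeffs = c(1, 0, 1e-3), horn_amplitude = 0.06,
                   horn_radius = 12, asym_x = 0.01, asym_y = 0.005)
  a2 <- simulate_cmn_acquisition(truth, b2, sc$geom, plan)
  s2 <- relative_sensitivity_at_points(a2, plan)
  expect_lt(max(abs(s1 - s2)), 5e-4)
  # a localized gain defect shows up at its sample point
  idx <- which(plan$points$x == 15 & plan$points$y == -15)
  expect_lt(s1[idx], 0.995)  # the blob at (16, -16) depresses this region
})

test_that("beam-response samples recover the fluence at the sample points", {
  sc <- exactness_scenario()
  truth <- exact_truth()
  plan <- cmn_plan()
  acq <- simulate_cmn_acquisition(truth, sc$beam, sc$geom, plan)
  s_rel <- relative_sensitivity_at_points(acq, plan)
  smp <- beam_response_samples(acq$wide, s_rel, plan)
  truth_at <- outer(smp$y, smp$x, function(y, x)
    beam_fluence(sc$beam, x, y, 40, 40))
  truth_at <- truth_at / truth_at[match(0, plan$y), match(0, plan$x)]
  expect_lt(max(abs(smp$values / truth_at - 1)), 1e-3)
  expect_error(beam_response_samples(acq$wide, s_rel[-1], plan), "per planned point")
  wide0 <- acq$wide; wide0$pixels <- matrix(0, nrow(wide0$pixels), ncol(wide0$pixels))
  expect_error(beam_response_samples(wide0, s_rel, plan), "no usable signal")
})

test_that("noiseless shifted-field pipeline recovers the PSM", {
  sc <- exactness_scenario(beam = bicubic_beam())
  truth <- scenario_truth(sc)
  fit <- fit_psm(simulate_cmn_acquisition(truth, sc$beam, sc$geom))
  dev <- percent_deviation_map(fit$psm, truth)
  inner <- inner_region(sc$geom, 15)
  expect_lt(median(abs(dev[inner & is.finite(dev)])), 0.05)
  # the dead-column band stays in the PSM, not the beam-response
  dcols <- which(colSums(truth$values == 0) > 200)
  expect_true(all(fit$psm$values[, dcols] < 0.1))
  # ... while the fitted beam-response stays smooth across it
  br_prof <- fit$beam_response$values[119, ]
  expect_lt(max(abs(diff(br_prof[dcols[1] - 3:0]))), 0.01)
  # identity: decomposing the beam-response by itself gives a flat PSM
  ident <- cmn_psm(raw_image(fit$beam_response$values, sc$geom, 100, 40, 40),
                   fit$beam_response)
  expect_lt(max(abs(ident$values[ident$valid_mask] - 1)), 1e-12)
})

test_that("extrapolation-zone recovery degrades relative to the interior", {
  fit <- noisy_fit("cmn")
  rep <- recovery_report(fit$psm, noisy_truth(), noisy_scenario()$geom)
  expect_gte(rep$bands[["15-20cm"]]$median_abs, rep$bands[["0-10cm"]]$median_abs)
})
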