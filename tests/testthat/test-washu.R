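test_that("ABDF averaging discards contaminated pairs and nets the rest", {
  geom <- small_geom(16L)
  bm <- bicubic_beam(0)
  ones <- matrix(1, 16, 16)
  # constant frames: net is beam minus dark
  pairs <- simulate_abdf_sequence(ones, bm, geom, n_pairs = 5, mu_per_frame = 2,
                                  noise = acquisition_noise(dark_offset = 7))
  avg <- abdf_average(pairs, n_discard = 2)
  expect_equal(avg$n_used, 3L)
  expect_equal(avg$net, 2 * beam_response_truth(bm, geom)$values,
               tolerance = 1e-12)
  # residual from a previous irradiation is confined to the discarded pairs
  pairs_r <- simulate_abdf_sequence(ones, bm, geom, n_pairs = 100,
                                    mu_per_frame = 2,
                                    initial_residual = matrix(1, 16, 16))
  avg_r <- abdf_average(pairs_r, n_discard = 40)
  expect_lt(max(abs(avg_r$net - 2 * beam_response_truth(bm, geom)$values)), 5e-6)
  expect_error(abdf_average(pairs, n_discard = 40), "more than n_discard")
})

test_that("shift plans require whole-pixel shifts and suggest the nearest", {
  geom <- panel_geometry(238, 238, 0.168)
  # the nominal 4 mm shift is 2.38 px here: refused, 0.336 cm suggested
  err <- tryCatch(washu_plan(4, geom), error = conditionMessage)
  expect_match(err, "whole pixels")
  expect_match(err, "0.3360")
  # full resolution: 4 mm is 11.9 px, nearest valid 12 px = 0.4032 cm
  err2 <- tryCatch(washu_plan(4, panel_geometry(1190, 1190, 0.0336)),
                   error = conditionMessage)
  expect_match(err2, "0.4032")
  plan <- washu_plan(10 * 2 * 0.168, geom)
  expect_equal(plan$shift_px, 2L)
  expect_equal(plan$shifts$lateral, c(0L, 2L))
  expect_equal(plan$shifts$longitudinal, c(2L, 0L))
})

test_that("propagation solves a hand-computed 1D sensitivity chain", {
  # panel of 4 columns with sensitivities s; one lateral shift of 1 px; any
  # positive beam. Expected recovery: s up to the seed scale.
  s <- c(1.0, 1.1, 0.9, 1.05)
  beam <- c(2.0, 2.2, 2.1, 1.9)
  nr <- 12L
  ref <- matrix(rep(s * beam, each = nr), nr, 4)
  # shifted acquisition: pixel (r, c) sees beam position c + 1
  lat <- matrix(rep(s * c(beam[-1], NA), each = nr), nr, 4)
  lat[, 4] <- 0  # no signal: beam position 5 is off the grid
  long <- ref    # longitudinal shift of 0 rows is not allowed; use 1 row
  long <- rbind(ref[-1, ], 0)
  rec <- suppressWarnings(recursive_sensitivity_propagation(
    ref, list(list(net = lat, dr = 0L, dc = 1L),
              list(net = long, dr = 1L, dc = 0L)),
    seed_halfwidth = 2L, threshold = 0.05))
  got <- rec$values[6, ]
  expect_equal(got / got[1], s / s[1], tolerance = 1e-12)
})

test_that("noiseless small-shift pipeline is exact and beam independent", {
  sc <- exactness_scenario()
  truth <- exact_truth()
  plan <- washu_plan(10 * 2 * sc$geom$pitch_iso, geom = sc$geom)
  acq <- simulate_washu_acquisition(truth, sc$beam, sc$geom, plan = plan,
                                    n_pairs = 2, residual_fraction = 0)
  fit <- suppressWarnings(fit_psm(acq, n_discard = 1))
  dev <- percent_deviation_map(fit$psm, truth)
  expect_lt(max(abs(dev[is.finite(dev)])), 1e-8)
  # the 37 cm field leaves the panel margin unconstrained
  g <- offaxis_grid(sc$geom)
  expect_true(all(!fit$psm$valid_mask[, abs(g$x) > 19.2]))
  # beam independence: wildly different horns/asymmetry, same PSM
  b2 <- beam_model(radial_coeffs = c(1, 0, 5e-4), horn_amplitude = 0.08,
                   asym_x = 0.01, asym_y = 0.008)
  acq2 <- simulate_washu_acquisition(truth, b2, sc$geom, plan = plan,
                                     n_pairs = 2, residual_fraction = 0)
  fit2 <- suppressWarnings(fit_psm(acq2, n_discard = 1))
  joint <- fit$psm$valid_mask & fit2$psm$valid_mask
  expect_lt(max(abs(fit2$psm$values[joint] - fit$psm$values[joint])), 1e-10)
  # the dead-pixel band is masked, not smoothed into the beam-response
  dcols <- which(colSums(truth$values == 0) > 200)
  expect_true(all(!fit$psm$valid_mask[, dcols]))
})

test_that("chain noise accumulates away from the seed region", {
  fit <- noisy_fit("washu")
  rep <- recovery_report(fit$psm, noisy_truth(), noisy_scenario()$geom)
  expect_gte(rep$bands[["15-20cm"]]$median_abs, rep$bands[["0-10cm"]]$median_abs)
  # repeated noisy runs: recovery-error spread grows with radius
  sc <- noisy_scenario()
  truth <- noisy_truth()
  r <- radius_map(sc$geom)
  sds <- sapply(c(31L, 57L), function(seed) {
    f <- suppressWarnings(fit_psm(simulate_method_acquisition(sc, "washu",
                                                              seed = seed,
                                                              n_pairs = 60L)))
    d <- percent_deviation_map(f$psm, truth)
    c(centre = sd(d[r < 8 & is.finite(d)]), edge = sd(d[r > 14 & is.finite(d)]))
  })
  expect_true(all(sds["edge", ] > sds["centre", ]))
})
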