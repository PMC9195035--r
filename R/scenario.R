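# Study scenarios: bundled simulator settings that define the conditions
# under which the four methods are exercised, plus the run-all driver that
# mirrors the full comparison (three repeats per method, recovery and
# repeatability reports, cross-method deviation tables against the radial
# method as reference).

#' Define a simulation scenario
#'
#' A scenario bundles the panel geometry, the beam model, the panel defect
#' model and the acquisition noise into one reproducible object. One base
#' seed fans out to per-acquisition subseeds with a fixed stride, so adding
#' an acquisition never perturbs earlier ones.
#'
#' @param geom a [panel_geometry()].
#' @param beam a [beam_model()].
#' @param defects a [panel_defect_model()].
#' @param noise an [acquisition_noise()].
#' @param name scenario label.
#' @return an object of class `psm_scenario`.
#' @export
scenario <- function(geom = panel_geometry(),
                     beam = beam_model(),
                     defects = panel_defect_model(),
                     noise = acquisition_noise(),
                     name = "scenario") {
  structure(list(geom = geom, beam = beam, defects = defects, noise = noise,
                 name = name),
            class = "psm_scenario")
}

# A dead-pixel band mirroring the clinical panel's dead columns (lateral
# offsets about -5.0 to -3.5 cm), expressed as 1-based column indices.
dead_band_columns <- function(geom, x_from = -5.04, x_to = -3.53) {
  g <- panel_frame(geom)
  which(g$x >= x_from & g$x <= x_to)
}

#' Default study scenario
#'
#' The textured noisy-panel conditions used throughout: 238 x 238 px (40 cm
#' span), flattened beam with horns, 0.3%/10 cm asymmetry and a corner
#' shadow; panel with a 3% smooth gain field, 2% static per-pixel spread, a
#' dead-column band near -4 cm lateral and two blob defects; 0.05% output
#' fluctuation and 0.1% readout noise.
#'
#' @param seed panel-texture seed.
#' @return a `psm_scenario`.
#' @export
default_scenario <- function(seed = 1L) {
  geom <- panel_geometry()
  scenario(geom = geom,
           beam = beam_model(),
           defects = panel_defect_model(
             smooth_gain_amplitude = 0.03, smooth_gain_corr_cm = 10,
             pixel_noise_sd = 0.02,
             dead_columns = dead_band_columns(geom),
             blob_defects = list(list(x = 11, y = -8, radius = 1.5, gain = 0.95),
                                 list(x = -9, y = 12, radius = 2, gain = 1.03)),
             seed = seed),
           noise = acquisition_noise(output_fluctuation_sd = 5e-4,
                                     readout_noise_sd = 1e-3,
                                     dark_offset = 10, lag_fraction = 0.02),
           name = "default-noisy")
}

#' Noiseless exactness scenario
#'
#' The scenario used to verify the estimation machinery itself: no
#' acquisition noise, and a panel whose centre is defect-free so the
#' propagation seed regions anchor every chain without approximation (the
#' dead-column band and blob defects sit away from the centre). The beam
#' keeps its horns, asymmetry and corner shadow unless overridden.
#'
#' @param beam a [beam_model()] override.
#' @return a `psm_scenario`.
#' @export
exactness_scenario <- function(beam = beam_model()) {
  geom <- panel_geometry()
  scenario(geom = geom, beam = beam,
           defects = panel_defect_model(
             smooth_gain_amplitude = 0, pixel_noise_sd = 0,
             dead_columns = dead_band_columns(geom),
             blob_defects = list(list(x = 16, y = -16, radius = 1.5, gain = 0.95)),
             seed = 1L),
           noise = acquisition_noise(),
           name = "noiseless-exactness")
}

#' Ground truth of a scenario
#'
#' @param sc a `psm_scenario`.
#' @return the normalized ground-truth [psm()].
#' @export
scenario_truth <- function(sc) generate_ground_truth_psm(sc$defects, sc$geom)

#' Simulate the acquisition set for one method under a scenario
#'
#' @param sc a `psm_scenario`.
#' @param method one of "cmn", "washu", "varian", "radial".
#' @param seed acquisition seed (the panel texture stays frozen by the
#'   scenario's defect seed).
#' @param washu_shift_px WashU shift step in pixels.
#' @param n_pairs ABDF pairs per sequence.
#' @return the method's acquisition object.
#' @export
simulate_method_acquisition <- function(sc, method = c("cmn", "washu",
                                                       "varian", "radial"),
                                        seed = 1L, washu_shift_px = 2L,
                                        n_pairs = 100L) {
  method <- match.arg(method)
  truth <- scenario_truth(sc)
  switch(method,
    cmn = simulate_cmn_acquisition(truth, sc$beam, sc$geom,
                                   noise = sc$noise, seed = seed),
    washu = {
      plan <- washu_plan(shift_mm = 10 * washu_shift_px * sc$geom$pitch_iso,
                         geom = sc$geom)
      simulate_washu_acquisition(truth, sc$beam, sc$geom, plan = plan,
                                 n_pairs = n_pairs, noise = sc$noise,
                                 seed = seed)
    },
    varian = simulate_varian_acquisition(truth, sc$beam, sc$geom,
                                         n_pairs = n_pairs,
                                         noise = sc$noise, seed = seed),
    radial = simulate_radial_acquisition(truth, sc$beam, sc$geom,
                                         noise = sc$noise, seed = seed))
}

#' Run the full four-method comparison
#'
#' Simulates `n_repeats` acquisitions per method under the scenario, fits
#' every repeat, and reports recovery against the simulator truth,
#' per-method repeatability, and cross-method deviation statistics with the
#' radial method as reference.
#'
#' @param sc a `psm_scenario`.
#' @param seed base seed; repeat r of method m uses
#'   `seed + 1000 * m + 100 * r`.
#' @param n_repeats successive determinations per method (>= 1;
#'   repeatability is skipped with a warning when 1).
#' @param methods methods to run.
#' @param n_pairs ABDF pairs per sequence.
#' @return object of class `psm_comparison`: per-method fits, recovery
#'   reports, repeatability maps and the cross-method table.
#' @export
run_all <- function(sc = default_scenario(), seed = 1L, n_repeats = 3L,
                    methods = c("cmn", "washu", "varian", "radial"),
                    n_pairs = 100L) {
  truth <- scenario_truth(sc)
  fits <- list(); recovery <- list(); repeats <- list()
  for (mi in seq_along(methods)) {
    m <- methods[mi]
    reps <- lapply(seq_len(n_repeats), function(r)
      fit_psm(simulate_method_acquisition(sc, m,
                                          seed = seed + 1000L * mi + 100L * r,
                                          n_pairs = n_pairs)))
    fits[[m]] <- reps[[1]]
    recovery[[m]] <- recovery_report(reps[[1]]$psm, truth, sc$geom)
    if (n_repeats >= 2L) {
      # the radial method determines its beam-response once and removes it
      # from successive raw images, so its repeatability measures the raw
      # image itself
      repeats[[m]] <- if (m == "radial")
        repeatability_map(radial_psm_repeats(sc, n_repeats,
                                             seed = seed + 1000L * mi))
      else
        repeatability_map(lapply(reps, function(f) f$psm))
    } else
      warning("n_repeats = 1: repeatability analysis skipped")
  }
  cross <- NULL
  if ("radial" %in% methods) {
    ref <- fits[["radial"]]$psm
    others <- setdiff(methods, "radial")
    cross <- do.call(rbind, lapply(others, function(m) {
      st <- deviation_stats(percent_deviation_map(fits[[m]]$psm, ref))
      data.frame(method = m, mean = st$mean, median = st$median, sd = st$sd,
                 p95_abs = st$p95_abs)
    }))
  }
  structure(list(scenario = sc$name, truth = truth, fits = fits,
                 recovery = recovery, repeatability = repeats,
                 cross_method = cross, seed = seed),
            class = "psm_comparison")
}

#' @export
print.psm_comparison <- function(x, ...) {
  cat(sprintf("PSM method comparison (%s, seed %d)\n", x$scenario, x$seed))
  for (m in names(x$recovery)) {
    st <- x$recovery[[m]]$stats
    cat(sprintf("  %-7s recovery: median %+.3f%%, median|dev| %.3f%%, SD %.3f%%",
                m, st$median, st$median_abs, st$sd))
    if (!is.null(x$repeatability[[m]]))
      cat(sprintf("; repeatability p95 %.3f%%", x$repeatability[[m]]$p95))
    cat("\n")
  }
  if (!is.null(x$cross_method)) {
    cat("  vs radial reference (median %):",
        paste(sprintf("%s %+0.3f", x$cross_method$method,
                      x$cross_method$median), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted repeatability p95 from readout-noise propagation
#'
#' For repeated raw images with per-pixel additive readout noise and a fixed
#' beam-response, the PSM repeatability per pixel is the readout SD relative
#' to the local signal; the sample SD over n repeats scales that by
#' `sqrt(chi2_{n-1}/(n-1))`. The predicted 95th percentile over pixels takes
#' both the spatial signal variation and the chi sampling spread into
#' account through a closed-form quantile of their product (independence,
#' with the chi quantile applied to the spatial mean level).
#'
#' @param sc a `psm_scenario`.
#' @param n_repeats number of repeats.
#' @return predicted p95 of the per-pixel CV, percent.
#' @export
predicted_repeatability_p95 <- function(sc, n_repeats = 3L) {
  br <- beam_response_truth(sc$beam, sc$geom, 40, 40)$values
  truth <- scenario_truth(sc)
  sig <- truth$values * br
  # dark-corrected images carry readout noise from the beam and the dark
  # frame, hence the sqrt(2)
  rel <- sqrt(2) * sc$noise$readout_noise_sd /
    sig[truth$valid_mask & sig > 0]
  chi_q <- sqrt(stats::qchisq(0.95, df = n_repeats - 1) / (n_repeats - 1))
  100 * stats::median(rel) * chi_q
}

#' Repeat the radial-method PSM with one fixed beam-response
#'
#' Mirrors the repeatability protocol of the transport-based method: the
#' beam-response is determined once, then removed from successive raw
#' images, so the spread measures the raw image's own stability.
#'
#' @param sc a `psm_scenario`.
#' @param n_repeats number of successive raw images.
#' @param seed base seed.
#' @return list of normalized [psm()]s.
#' @export
radial_psm_repeats <- function(sc, n_repeats = 3L, seed = 1L) {
  truth <- scenario_truth(sc)
  acq <- simulate_radial_acquisition(truth, sc$beam, sc$geom,
                                     noise = sc$noise, seed = seed)
  fn <- smooth_radial_fit(radial_ring_average(acq$ideal))
  lapply(seq_len(n_repeats), function(r) {
    meas <- render_net_image(truth, sc$beam, sc$geom, mu = 100,
                             noise = sc$noise, seed = seed + 10L * r)
    radial_psm(meas, fn)
  })
}
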