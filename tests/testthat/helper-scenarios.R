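# Shared fixtures, built lazily so each heavy simulation runs once per
# session no matter how many test files use it.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a beam whose 2D response is a bicubic polynomial inside the field, hence
# exactly representable by the tensor-product cubic spline
bicubic_beam <- function(asym = 0.002)
  beam_model(radial_coeffs = c(1, 0, 2e-4), horn_amplitude = 0,
             asym_x = asym, asym_y = asym, shadow_depth = 0)

exact_truth <- function() fixture("exact_truth", function()
  scenario_truth(exactness_scenario()))

noisy_scenario <- function() fixture("noisy_scenario", default_scenario)

noisy_truth <- function() fixture("noisy_truth", function()
  scenario_truth(noisy_scenario()))

noisy_fit <- function(method) fixture(paste0("noisy_fit_", method), function()
  suppressWarnings(fit_psm(simulate_method_acquisition(noisy_scenario(),
                                                       method, seed = 11L))))

# small geometry for cheap component tests
small_geom <- function(n = 60L) panel_geometry(n, n, pitch_iso = 40 / n)

inner_region <- function(geom, half = 15) {
  g <- offaxis_grid(geom)
  outer(abs(g$y) <= half, abs(g$x) <= half, "&")
}

radius_map <- function(geom) {
  g0 <- panel_geometry(geom$n_rows, geom$n_cols, geom$pitch_iso)
  g <- offaxis_grid(g0)
  sqrt(outer(g$y^2, g$x^2, "+"))
}
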