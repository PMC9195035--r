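# Radially symmetric beam-response method: a noisy idealized image (the
# analogue of a first-principles transport calculation of an optimally
# steered beam, with no panel in the way) is averaged over concentric rings,
# the ring profile is smoothed, and the resulting symmetric beam-response is
# removed from a measured raw image to yield the PSM. By construction the
# method cannot represent any beam asymmetry, which therefore leaks into the
# PSM - a documented idealization bias, not a defect of the implementation.

#' Concentric-ring average of an image
#'
#' Bins pixels by radius from the array centre into rings
#' `[k*w, (k+1)*w)` and reports per-ring means and pixel counts. Rings whose
#' radius exceeds the panel half-width are only partially on the panel and
#' are flagged.
#'
#' @param img matrix or [raw_image()].
#' @param geom a [panel_geometry()]; taken from `img` when possible.
#' @param ring_width ring spacing in cm (default 0.5).
#' @return object of class `radial_profile`: data.frame with `r` (ring
#'   centre, cm), `mean`, `count`, `partial`.
#' @export
radial_ring_average <- function(img, geom = NULL, ring_width = 0.5) {
  if (ring_width <= 0) stop("ring_width must be positive")
  if (inherits(img, "raw_image")) {
    if (is.null(geom)) geom <- img$geometry
    img <- img$pixels
  }
  img <- as.matrix(img)
  if (is.null(geom))
    geom <- panel_geometry(nrow(img), ncol(img), pitch_iso = 40 / ncol(img))
  g <- panel_frame(geom)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  bin <- floor(r / ring_width)
  counts <- tabulate(bin + 1L)
  sums <- rowsum(as.vector(img), as.vector(bin))
  ks <- as.integer(rownames(sums))
  half_width <- min(max(abs(g$x)), max(abs(g$y)))
  out <- data.frame(r = (ks + 0.5) * ring_width,
                    mean = as.vector(sums) / counts[ks + 1L],
                    count = counts[ks + 1L])
  out$partial <- (out$r + ring_width / 2) > half_width
  structure(out, class = c("radial_profile", "data.frame"))
}

#' Smooth fit to a ring-averaged profile
#'
#' Weighted smoothing spline in radius, with ring pixel counts as weights
#' (inner rings average few pixels and stay noisy; outer full rings are
#' precise) and the smoothing parameter chosen by generalized
#' cross-validation. The returned function extrapolates linearly beyond the
#' outermost ring.
#'
#' @param profile a [radial_ring_average()] result (needs >= 8 rings).
#' @return function mapping radius (cm) to relative beam-response.
#' @export
smooth_radial_fit <- function(profile) {
  if (nrow(profile) < 8L)
    stop("too few rings for a stable smooth fit (need at least 8)")
  fit <- stats::smooth.spline(profile$r, profile$mean, w = profile$count)
  function(r) stats::predict(fit, as.vector(r))$y
}

#' PSM from a raw image and a radial beam-response function
#'
#' Builds the beam-response map by evaluating the radial function at every
#' pixel's radius and decomposes the raw image against it.
#'
#' @param raw a measured [raw_image()] (centered).
#' @param radial_fn function of radius from [smooth_radial_fit()].
#' @param geom a [panel_geometry()]; taken from `raw` when possible.
#' @return a normalized [psm()].
#' @export
radial_psm <- function(raw, radial_fn, geom = NULL) {
  if (is.null(geom)) geom <- raw$geometry
  g <- panel_frame(geom)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  br <- beam_response(matrix(radial_fn(r), nrow(r), ncol(r)),
                      provenance = "radial_fit")
  decompose_image(raw, br)
}

#' Simulate the idealized + measured image pair for the radial method
#'
#' The idealized image is a render of the beam's symmetric component through
#' a perfectly uniform panel with heavy per-pixel statistical noise (the
#' stand-in for a transport calculation whose per-pixel variance is large);
#' the measured image is an ordinary raw acquisition of the true panel under
#' the full beam.
#'
#' @param psm_true ground-truth [psm()].
#' @param beam a [beam_model()]; the ideal image uses
#'   [symmetric_component()] of it.
#' @param geom centered [panel_geometry()].
#' @param ideal_noise_sd per-pixel fractional noise of the idealized image.
#' @param noise an [acquisition_noise()] for the measured image.
#' @param mu monitor units of the measured image.
#' @param seed base seed.
#' @return list of class `radial_acquisition` with `ideal` and `measured`.
#' @export
simulate_radial_acquisition <- function(psm_true, beam, geom,
                                        ideal_noise_sd = 0.01,
                                        noise = noiseless(), mu = 100,
                                        seed = 1L) {
  ones <- matrix(1, geom$n_rows, geom$n_cols)
  ideal <- render_raw_image(ones, symmetric_component(beam), geom, mu = 1,
                            field_x = 40, field_y = 40,
                            noise = acquisition_noise(readout_noise_sd = ideal_noise_sd),
                            seed = seed)
  measured <- render_net_image(psm_true, beam, geom, mu = mu,
                               field_x = 40, field_y = 40,
                               noise = noise, seed = seed + 1L)
  structure(list(ideal = ideal, measured = measured, geometry = geom),
            class = "radial_acquisition")
}
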