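# Parametric model of the beam-introduced non-uniformity as recorded by an
# ideal uniform-sensitivity imager: a flattened photon beam with off-axis
# horns, a small clinically-acceptable asymmetry, collimated field edges with
# Gaussian-like penumbra, and a primary-collimator corner shadow.

#' Parametric beam model
#'
#' Relative fluence in the isocenter plane:
#' \deqn{f(x,y) = P(r)\,(1 + A e^{-(r-r_h)^2/2\sigma_h^2})
#'   (1 + a_x x/10)(1 + a_y y/10)\,E(x,y)\,S(r)}
#' where `P` is the radial polynomial, the Gaussian bump the EPID-exaggerated
#' flattening-filter horns, `a_x`/`a_y` fractional linear tilts per 10 cm,
#' `E` the field-edge sigmoid (penumbra) and `S` a radial sigmoid shadow from
#' the primary collimator reaching the panel corners.
#'
#' @param radial_coeffs polynomial coefficients of relative fluence vs radius
#'   r in cm (constant term first); must equal 1 at r = 0.
#' @param horn_amplitude relative amplitude of the horn bump.
#' @param horn_radius,horn_sigma centre (cm) and width (cm) of the horn bump.
#' @param asym_x,asym_y fractional linear tilt per 10 cm.
#' @param penumbra_sigma field-edge sigmoid scale, cm.
#' @param shadow_onset,shadow_falloff,shadow_depth corner-shadow radial
#'   sigmoid: onset radius (cm), falloff scale (cm) and depth (fraction).
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(radial_coeffs = c(1, 0, 2e-4, -2e-6),
                       horn_amplitude = 0.025, horn_radius = 16,
                       horn_sigma = 4,
                       asym_x = 0.003, asym_y = 0,
                       penumbra_sigma = 0.3,
                       shadow_onset = 26, shadow_falloff = 1.5,
                       shadow_depth = 0.2) {
  if (abs(radial_coeffs[1] - 1) > 1e-12)
    stop("radial polynomial must equal 1 on the beam axis")
  structure(list(radial_coeffs = radial_coeffs,
                 horn_amplitude = horn_amplitude, horn_radius = horn_radius,
                 horn_sigma = horn_sigma, asym_x = asym_x, asym_y = asym_y,
                 penumbra_sigma = penumbra_sigma,
                 shadow_onset = shadow_onset,
                 shadow_falloff = shadow_falloff,
                 shadow_depth = shadow_depth),
            class = "beam_model")
}

#' Strip the non-radial terms from a beam model
#'
#' Returns the idealised, radially symmetric component of a beam model
#' (asymmetry tilts set to zero), the component a first-principles
#' transport calculation of an optimally steered beam would see.
#'
#' @param model a [beam_model()].
#' @return a [beam_model()] with `asym_x = asym_y = 0`.
#' @export
symmetric_component <- function(model) {
  model$asym_x <- 0
  model$asym_y <- 0
  model
}

#' Evaluate relative beam fluence
#'
#' @param model a [beam_model()].
#' @param x,y off-axis position in cm at isocenter (vectorised; recycled).
#' @param field_x,field_y collimated field size at isocenter, cm.
#' @return relative fluence, 1 on the axis for a symmetric model.
#' @export
beam_fluence <- function(model, x, y, field_x = 40, field_y = 40) {
  r <- sqrt(x^2 + y^2)
  p <- 0
  for (k in rev(seq_along(model$radial_coeffs)))
    p <- p * r + model$radial_coeffs[k]
  horn <- 1 + model$horn_amplitude *
    exp(-(r - model$horn_radius)^2 / (2 * model$horn_sigma^2))
  # subtract the on-axis residue of the bump so the axis value stays 1
  horn0 <- 1 + model$horn_amplitude *
    exp(-model$horn_radius^2 / (2 * model$horn_sigma^2))
  asym <- (1 + model$asym_x * x / 10) * (1 + model$asym_y * y / 10)
  s <- model$penumbra_sigma
  edge <- stats::plogis((field_x / 2 - abs(x)) / s) *
    stats::plogis((field_y / 2 - abs(y)) / s)
  edge0 <- stats::plogis((field_x / 2) / s) * stats::plogis((field_y / 2) / s)
  shadow <- 1 - model$shadow_depth *
    stats::plogis((r - model$shadow_onset) / model$shadow_falloff)
  shadow0 <- 1 - model$shadow_depth *
    stats::plogis(-model$shadow_onset / model$shadow_falloff)
  p * (horn / horn0) * asym * (edge / edge0) * (shadow / shadow0)
}

#' Beam-response truth map on a panel grid
#'
#' Evaluates a beam model at every pixel's beam-frame position (including the
#' panel shift and SID magnification carried by the geometry).
#'
#' @param model a [beam_model()].
#' @param geom a [panel_geometry()].
#' @param field_x,field_y field size at isocenter, cm.
#' @return a [beam_response()] with provenance `"simulator_truth"`.
#' @export
beam_response_truth <- function(model, geom, field_x = 40, field_y = 40) {
  g <- offaxis_grid(geom)
  vals <- outer(g$y, g$x, function(yy, xx)
    beam_fluence(model, xx, yy, field_x, field_y))
  beam_response(vals, provenance = "simulator_truth")
}
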