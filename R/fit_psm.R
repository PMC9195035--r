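# Front end: one fitting function over the four estimation methods,
# returning a classed object with the usual accessor methods.

#' Fit a pixel-sensitivity map from an acquisition set
#'
#' Dispatches on the acquisition class (`cmn_acquisition`,
#' `washu_acquisition`, `varian_acquisition`, `radial_acquisition`) and runs
#' the corresponding estimation pipeline:
#' \describe{
#'   \item{cmn}{shifted small-field sensitivities, 2D not-a-knot spline
#'     beam-response fit with linear extrapolation, division of the
#'     wide-field image;}
#'   \item{washu}{ABDF-averaged small-shift large fields, recursive
#'     pixel-ratio propagation;}
#'   \item{varian}{50-pixel-shift propagation, two-SID low-frequency
#'     correction, four-quadrant polynomial tuning;}
#'   \item{radial}{concentric-ring averaging of an idealized symmetric
#'     image, weighted smoothing-spline radial fit, division of the
#'     measured image.}
#' }
#'
#' @param acquisition an acquisition object from one of the
#'   `simulate_*_acquisition()` builders (or assembled from loaded images
#'   with the same structure).
#' @param ... passed to the method pipeline (e.g. `n_discard`,
#'   `seed_halfwidth`, `ring_width`).
#' @return an object of class `psm_fit` with elements `psm` (normalized
#'   [psm()]), `beam_response` (the method's beam-response on the panel grid
#'   where the method produces one directly), `method` and `diagnostics`.
#' @export
fit_psm <- function(acquisition, ...) UseMethod("fit_psm")

#' @export
fit_psm.cmn_acquisition <- function(acquisition, ...) {
  s_rel <- relative_sensitivity_at_points(acquisition, acquisition$plan)
  samples <- beam_response_samples(acquisition$wide, s_rel, acquisition$plan)
  br <- fit_beam_response_2d(samples, acquisition$wide$geometry)
  p <- cmn_psm(acquisition$wide, br)
  new_psm_fit(p, method = "cmn", beam_response = br,
              diagnostics = list(s_rel = s_rel, samples = samples))
}

#' @export
fit_psm.washu_acquisition <- function(acquisition, ...) {
  p <- washu_psm(acquisition, ...)
  new_psm_fit(p, method = "washu",
              diagnostics = list(plan = acquisition$plan))
}

#' @export
fit_psm.varian_acquisition <- function(acquisition, ...) {
  vf <- varian_psm(acquisition, ...)
  new_psm_fit(vf$psm, method = "varian",
              diagnostics = list(stage1_psm = vf$stage1_psm,
                                 stage2_rms = vf$stage2_rms,
                                 stage3_rms = vf$stage3_rms))
}

#' @export
fit_psm.radial_acquisition <- function(acquisition, ring_width = 0.5, ...) {
  prof <- radial_ring_average(acquisition$ideal, ring_width = ring_width)
  fn <- smooth_radial_fit(prof)
  p <- radial_psm(acquisition$measured, fn)
  g <- panel_frame(acquisition$measured$geometry)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  br <- normalize_beam_response(
    beam_response(matrix(fn(r), nrow(r), ncol(r)), provenance = "radial_fit"))
  new_psm_fit(p, method = "radial", beam_response = br,
              diagnostics = list(profile = prof))
}

new_psm_fit <- function(p, method, beam_response = NULL, diagnostics = list()) {
  structure(list(psm = p, beam_response = beam_response, method = method,
                 diagnostics = diagnostics),
            class = "psm_fit")
}

#' @export
print.psm_fit <- function(x, ...) {
  cat(sprintf("PSM fit (%s method)\n", x$method))
  print(x$psm)
  invisible(x)
}

#' @export
summary.psm_fit <- function(object, truth = NULL, ...) {
  v <- object$psm$values[object$psm$valid_mask]
  out <- list(method = object$method,
              n_valid = sum(object$psm$valid_mask),
              n_masked = sum(!object$psm$valid_mask),
              range = range(v), sd = stats::sd(v))
  if (!is.null(truth))
    out$recovery <- recovery_report(object$psm, truth)
  structure(out, class = "summary.psm_fit")
}

#' @export
print.summary.psm_fit <- function(x, ...) {
  cat(sprintf("PSM fit (%s): %d valid px (%d masked), values in [%.4f, %.4f], SD %.4f\n",
              x$method, x$n_valid, x$n_masked, x$range[1], x$range[2], x$sd))
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}

#' @export
plot.psm_fit <- function(x, what = c("psm", "beam_response"), ...) {
  what <- match.arg(what)
  m <- if (what == "psm") x$psm$values else {
    if (is.null(x$beam_response))
      stop("this method does not produce a beam-response map directly")
    x$beam_response$values
  }
  graphics::image(t(m)[, nrow(m):1], asp = 1, axes = FALSE, useRaster = TRUE,
                  main = sprintf("%s (%s method)", what, x$method), ...)
  invisible(x)
}

#' Residual beam-response of a fitted PSM
#'
#' Removing the fitted PSM from a raw image leaves the method's implied
#' beam-response; this is how the PSM-first methods yield a beam-response
#' for cross-method comparison.
#'
#' @param object a `psm_fit`.
#' @param raw a centered wide-field [raw_image()].
#' @param ... unused.
#' @return a [beam_response()], central-axis normalized.
#' @export
residuals.psm_fit <- function(object, raw, ...) {
  pv <- object$psm$values
  v <- matrix(NA_real_, nrow(pv), ncol(pv))
  ok <- pv > 0
  v[ok] <- raw$pixels[ok] / pv[ok]
  v[!ok] <- 0
  normalize_beam_response(beam_response(v, provenance = "sampled_grid"))
}
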