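# Shifted-field method ("CMN"): a constant small field imaged at a grid of
# panel offsets gives the relative sensitivity at each sampled panel point
# (the beam cancels in the ratio to the centered acquisition). Dividing a
# wide-field raw image by those sensitivities yields beam-response samples,
# which a tensor-product not-a-knot spline (with linear extrapolation to the
# panel edge) turns into a full beam-response map; removing that from the
# wide-field image gives the PSM for every pixel.

# panel-frame coordinates of an image's pixels (shift removed)
panel_frame <- function(geom)
  offaxis_grid(panel_geometry(geom$n_rows, geom$n_cols, geom$pitch_iso))

# area-weighted mean over the square [px +- hw] x [py +- hw]: pixels at the
# ROI boundary contribute fractionally, so the ROI is exactly centred on the
# nominal point regardless of grid alignment (whole-pixel ROIs would sit up
# to half a pixel off-centre and break the beam cancellation)
roi_mean <- function(pixels, geom, px, py, halfwidth) {
  g <- panel_frame(geom)
  h <- geom$pitch_iso / 2
  wx <- pmax(0, pmin(g$x + h, px + halfwidth) - pmax(g$x - h, px - halfwidth))
  wy <- pmax(0, pmin(g$y + h, py + halfwidth) - pmax(g$y - h, py - halfwidth))
  if (sum(wx) == 0 || sum(wy) == 0) stop("ROI falls outside the panel")
  w <- outer(wy, wx)
  sum(w * pixels) / sum(w)
}

#' Panel-offset sampling plan for the shifted-field method
#'
#' The default samples a 7 x 6 grid of panel points at 5 cm intervals,
#' lateral -15 to +15 cm and longitudinal -15 to +10 cm (the panel cannot
#' travel further in one longitudinal direction), i.e. 42 offset acquisitions
#' plus the centered reference. A sample at panel point p is acquired by
#' shifting the panel by -p so the beam axis lands on p.
#'
#' @param lat_range,long_range two-element ranges in cm, multiples of `step`.
#' @param step sample spacing in cm (> 0).
#' @param roi_halfwidth half-width of the square sampling ROI, cm.
#' @param field small-field size, cm (square).
#' @param penumbra_sigma assumed field-edge penumbra scale, cm; the ROI must
#'   stay `3 * penumbra_sigma` clear of the field edge.
#' @return an object of class `offset_plan` with a data.frame `points`
#'   (sample point and panel shift per acquisition).
#' @export
cmn_plan <- function(lat_range = c(-15, 15), long_range = c(-15, 10),
                     step = 5, roi_halfwidth = 0.5, field = 5,
                     penumbra_sigma = 0.3) {
  if (step <= 0) stop("step must be positive")
  if (any(abs(c(lat_range, long_range) / step -
              round(c(lat_range, long_range) / step)) > 1e-9))
    stop("ranges must be integer multiples of step")
  if (roi_halfwidth > field / 2 - 3 * penumbra_sigma)
    stop("ROI touches the field penumbra: reduce roi_halfwidth or enlarge the field")
  xs <- seq(lat_range[1], lat_range[2], by = step)
  ys <- seq(long_range[1], long_range[2], by = step)
  pts <- expand.grid(x = xs, y = ys)
  structure(list(points = data.frame(x = pts$x, y = pts$y,
                                     shift_x = -pts$x, shift_y = -pts$y),
                 x = xs, y = ys,
                 roi_halfwidth = roi_halfwidth, field = field,
                 penumbra_sigma = penumbra_sigma),
            class = "offset_plan")
}

#' @export
print.offset_plan <- function(x, ...) {
  cat(sprintf("offset plan: %d sample points (%d x %d grid), %g x %g cm field, ROI halfwidth %g cm\n",
              nrow(x$points), length(x$x), length(x$y), x$field, x$field,
              x$roi_halfwidth))
  invisible(x)
}

#' Relative pixel sensitivities at the sampled panel points
#'
#' For each planned offset, the small-field image (beam axis on panel point
#' p) is ROI-averaged at p and divided by the centered reference image's ROI
#' average at the panel centre. The beam profile cancels in the ratio, so in
#' the absence of noise the result is exactly the ROI-averaged PSM ratio.
#'
#' @param images list with `reference` (centered [raw_image()]) and
#'   `offsets`, a list of [raw_image()]s parallel to `plan$points`.
#' @param plan an [cmn_plan()].
#' @return numeric vector of relative sensitivities, one per sample point.
#' @export
relative_sensitivity_at_points <- function(images, plan) {
  ref <- images$reference
  if (length(images$offsets) != nrow(plan$points))
    stop("one offset image per planned point is required")
  hw <- plan$roi_halfwidth
  ref_mean <- roi_mean(ref$pixels, ref$geometry, 0, 0, hw)
  if (ref_mean <= 0) stop("centered reference ROI has no signal")
  vapply(seq_len(nrow(plan$points)), function(k) {
    img <- images$offsets[[k]]
    roi_mean(img$pixels, img$geometry,
             plan$points$x[k], plan$points$y[k], hw) / ref_mean
  }, numeric(1))
}

#' Beam-response samples from a wide-field image
#'
#' Divides ROI averages of a centered wide-field raw image at each sampled
#' panel point by the relative sensitivities, normalized to the (0, 0) point.
#'
#' @param wide_raw centered wide-field [raw_image()].
#' @param s_rel relative sensitivities from
#'   [relative_sensitivity_at_points()].
#' @param plan the [cmn_plan()] used.
#' @return object of class `sampled_beam_response`: sample axes `x`, `y` and
#'   a `length(y) x length(x)` matrix `values`.
#' @export
beam_response_samples <- function(wide_raw, s_rel, plan) {
  if (length(s_rel) != nrow(plan$points))
    stop("one sensitivity per planned point is required")
  if (abs(wide_raw$geometry$shift_x) > 1e-9 ||
      abs(wide_raw$geometry$shift_y) > 1e-9)
    stop("wide-field image must be acquired with the panel centered")
  hw <- plan$roi_halfwidth
  br <- vapply(seq_len(nrow(plan$points)), function(k)
    roi_mean(wide_raw$pixels, wide_raw$geometry,
             plan$points$x[k], plan$points$y[k], hw) / s_rel[k],
    numeric(1))
  if (any(!is.finite(br)) || all(br == 0))
    stop("wide-field image carries no usable signal at the sample points")
  vals <- matrix(NA_real_, length(plan$y), length(plan$x))
  ix <- match(plan$points$x, plan$x)
  iy <- match(plan$points$y, plan$y)
  vals[cbind(iy, ix)] <- br
  i0x <- match(0, plan$x); i0y <- match(0, plan$y)
  if (!is.na(i0x) && !is.na(i0y)) vals <- vals / vals[i0y, i0x]
  structure(list(x = plan$x, y = plan$y, values = vals),
            class = "sampled_beam_response")
}

#' PSM from a wide-field image and a fitted beam-response
#'
#' @param wide_raw centered wide-field [raw_image()].
#' @param br_fit a [beam_response()] on the panel grid.
#' @return a normalized [psm()].
#' @export
cmn_psm <- function(wide_raw, br_fit) {
  decompose_image(wide_raw, br_fit)
}

#' Simulate a complete shifted-field acquisition
#'
#' Renders the centered small-field reference, one small-field image per
#' planned offset, and the centered wide-field image.
#'
#' @param psm_true ground-truth [psm()].
#' @param beam a [beam_model()].
#' @param geom centered [panel_geometry()].
#' @param plan an [cmn_plan()].
#' @param noise an [acquisition_noise()].
#' @param mu monitor units per small-field image.
#' @param mu_wide monitor units for the wide-field image.
#' @param wide_field wide-field size, cm.
#' @param seed base seed; acquisitions use `seed + k` for fixed strides k.
#' @return list of class `cmn_acquisition`.
#' @export
simulate_cmn_acquisition <- function(psm_true, beam, geom, plan = cmn_plan(),
                                     noise = noiseless(), mu = 100,
                                     mu_wide = 100, wide_field = 40,
                                     seed = 1L) {
  f <- plan$field
  ref <- render_net_image(psm_true, beam, geom, mu = mu,
                          field_x = f, field_y = f, noise = noise,
                          seed = seed)
  offs <- lapply(seq_len(nrow(plan$points)), function(k) {
    gk <- geom
    gk$shift_x <- plan$points$shift_x[k]
    gk$shift_y <- plan$points$shift_y[k]
    render_net_image(psm_true, beam, gk, mu = mu,
                     field_x = f, field_y = f, noise = noise,
                     seed = seed + k)
  })
  wide <- render_net_image(psm_true, beam, geom, mu = mu_wide,
                           field_x = wide_field, field_y = wide_field,
                           noise = noise, seed = seed + nrow(plan$points) + 1L)
  structure(list(reference = ref, offsets = offs, wide = wide, plan = plan),
            class = "cmn_acquisition")
}
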