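# Synthetic EPID acquisition engine: ground-truth pixel-sensitivity maps with
# realistic defect structure, raw-image rendering (shift, SID, MU, noise) and
# alternating beam/dark field (ABDF) frame sequences.
#
# Seeding: every stochastic routine takes an explicit `seed`; the panel's
# static pixel texture is frozen by the defect-model seed (a property of the
# panel), while readout noise and output fluctuations are redrawn per frame /
# per irradiation from the acquisition seed. Scenario code fans one base seed
# out with a fixed counter stride so adding an acquisition never perturbs
# earlier ones.

#' Panel defect model
#'
#' Static, multiplicative structure of the imager: a low-spatial-frequency
#' gain field, per-pixel static sensitivity spread, dead pixel columns and
#' localized blob defects.
#'
#' @param smooth_gain_amplitude fractional SD of the smooth gain field.
#' @param smooth_gain_corr_cm correlation length of the smooth field, cm.
#' @param pixel_noise_sd fractional SD of the static per-pixel sensitivity
#'   spread.
#' @param dead_columns integer column indices (1-based) that are dead (gain 0).
#' @param blob_defects list of `list(x=, y=, radius=, gain=)` entries: smooth
#'   circular gain patches centred at (x, y) cm with the given radius (cm) and
#'   central gain factor.
#' @param seed integer; freezes the panel texture.
#' @return an object of class `panel_defect_model`.
#' @export
panel_defect_model <- function(smooth_gain_amplitude = 0.03,
                               smooth_gain_corr_cm = 10,
                               pixel_noise_sd = 0.02,
                               dead_columns = integer(0),
                               blob_defects = list(),
                               seed = 1L) {
  structure(list(smooth_gain_amplitude = smooth_gain_amplitude,
                 smooth_gain_corr_cm = smooth_gain_corr_cm,
                 pixel_noise_sd = pixel_noise_sd,
                 dead_columns = as.integer(dead_columns),
                 blob_defects = blob_defects,
                 seed = as.integer(seed)),
            class = "panel_defect_model")
}

#' Acquisition noise model
#'
#' @param output_fluctuation_sd fractional SD of the per-irradiation machine
#'   output factor (one global scale per beam-on frame).
#' @param readout_noise_sd per-pixel, per-frame additive readout noise,
#'   expressed as a fraction of the central open-field signal.
#' @param dark_offset constant dark-frame offset, counts.
#' @param lag_fraction fraction of the previous frame carried into the next
#'   (image lag / ghosting).
#' @return an object of class `acquisition_noise`.
#' @export
acquisition_noise <- function(output_fluctuation_sd = 0,
                              readout_noise_sd = 0,
                              dark_offset = 0,
                              lag_fraction = 0) {
  if (output_fluctuation_sd < 0 || readout_noise_sd < 0 ||
      dark_offset < 0 || lag_fraction < 0)
    stop("noise parameters must be non-negative")
  structure(list(output_fluctuation_sd = output_fluctuation_sd,
                 readout_noise_sd = readout_noise_sd,
                 dark_offset = dark_offset,
                 lag_fraction = lag_fraction),
            class = "acquisition_noise")
}

#' @rdname acquisition_noise
#' @export
noiseless <- function() acquisition_noise()

# Low-spatial-frequency random surface: sum of random plane-wave cosines with
# wavelengths no shorter than the correlation length, scaled to unit SD.
smooth_random_field <- function(xs, ys, corr_cm, n_waves = 12L) {
  f <- matrix(0, length(ys), length(xs))
  for (k in seq_len(n_waves)) {
    ang <- stats::runif(1, 0, 2 * pi)
    freq <- stats::runif(1, 0.1, 1) / corr_cm
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * cos(2 * pi * freq *
                         outer(ys * sin(ang), xs * cos(ang), "+") + ph)
  }
  f / sqrt(n_waves / 2)  # each wave contributes variance amp^2/2
}

#' Generate a ground-truth pixel-sensitivity map
#'
#' PSM = smooth gain field x (1 + static pixel noise), with dead columns
#' zeroed and blob defects applied, renormalized to the central 10 x 10 ROI.
#' Deterministic for a fixed defect-model seed.
#'
#' @param defects a [panel_defect_model()].
#' @param geom a [panel_geometry()].
#' @return a normalized [psm()]; dead pixels have value 0 and
#'   `valid_mask` FALSE.
#' @export
generate_ground_truth_psm <- function(defects, geom) {
  g <- offaxis_grid(panel_geometry(geom$n_rows, geom$n_cols, geom$pitch_iso))
  set.seed(defects$seed)
  vals <- matrix(1, geom$n_rows, geom$n_cols)
  if (defects$smooth_gain_amplitude > 0)
    vals <- vals * (1 + defects$smooth_gain_amplitude *
                      smooth_random_field(g$x, g$y, defects$smooth_gain_corr_cm))
  if (defects$pixel_noise_sd > 0)
    vals <- vals * (1 + defects$pixel_noise_sd *
                      matrix(stats::rnorm(length(vals)),
                             nrow(vals), ncol(vals)))
  for (b in defects$blob_defects) {
    d2 <- outer((g$y - b$y)^2, (g$x - b$x)^2, "+")
    vals <- vals * (1 + (b$gain - 1) * exp(-d2 / (2 * (b$radius / 2)^2)))
  }
  vals[vals < 0] <- 0
  mask <- matrix(TRUE, geom$n_rows, geom$n_cols)
  if (length(defects$dead_columns)) {
    vals[, defects$dead_columns] <- 0
    mask[, defects$dead_columns] <- FALSE
  }
  normalize_psm(psm(vals, valid_mask = mask))
}

#' Render a raw EPID image
#'
#' Noiseless signal is `mu * o * psm * BR(x, y) * (sid_ref/sid)^2` where `o`
#' is the per-irradiation output factor and (x, y) the pixel's beam-frame
#' position including panel shift and SID magnification; readout noise and a
#' dark offset are added on top. Deterministic per seed.
#'
#' @param psm_true a [psm()] (or matrix) of per-pixel gains.
#' @param beam a [beam_model()].
#' @param geom a [panel_geometry()] (carries shift and SID).
#' @param mu monitor units (> 0 scales the signal).
#' @param field_x,field_y collimated field at isocenter, cm.
#' @param noise an [acquisition_noise()].
#' @param seed integer seed for the stochastic terms.
#' @return a [raw_image()] of kind "beam".
#' @export
render_raw_image <- function(psm_true, beam, geom, mu = 100,
                             field_x = 40, field_y = 40,
                             noise = noiseless(), seed = 1L) {
  if (mu < 0) stop("mu must be non-negative")
  pv <- if (inherits(psm_true, "psm")) psm_true$values else as.matrix(psm_true)
  if (nrow(pv) != geom$n_rows || ncol(pv) != geom$n_cols)
    stop("psm shape does not match geometry")
  br <- beam_response_truth(beam, geom, field_x, field_y)$values
  scale <- mu * (geom$sid_ref / geom$sid)^2
  set.seed(seed)
  o <- if (noise$output_fluctuation_sd > 0)
    1 + noise$output_fluctuation_sd * stats::rnorm(1) else 1
  sig <- scale * o * pv * br
  if (noise$readout_noise_sd > 0)
    sig <- sig + noise$readout_noise_sd * scale *
      matrix(stats::rnorm(length(sig)), nrow(sig), ncol(sig))
  sig <- sig + noise$dark_offset
  raw_image(pmax(sig, 0), geom, mu = mu,
            field_x = field_x, field_y = field_y, kind = "beam")
}

#' Render a dark-corrected raw image
#'
#' Renders a beam frame and an immediately following dark frame with the
#' same noise model and returns their difference (what a clinical
#' acquisition system delivers: the dark offset removed, readout noise from
#' both frames retained).
#'
#' @inheritParams render_raw_image
#' @return a [raw_image()] of kind "net".
#' @export
render_net_image <- function(psm_true, beam, geom, mu = 100,
                             field_x = 40, field_y = 40,
                             noise = noiseless(), seed = 1L) {
  bframe <- render_raw_image(psm_true, beam, geom, mu = mu,
                             field_x = field_x, field_y = field_y,
                             noise = noise, seed = seed)
  dark <- noise$dark_offset
  if (noise$readout_noise_sd > 0) {
    set.seed(seed + 500000L)
    dark <- dark + noise$readout_noise_sd * mu * (geom$sid_ref / geom$sid)^2 *
      matrix(stats::rnorm(geom$n_rows * geom$n_cols), geom$n_rows, geom$n_cols)
  }
  raw_image(bframe$pixels - dark, geom, mu = mu,
            field_x = field_x, field_y = field_y, kind = "net")
}

#' Simulate an alternating beam/dark field (ABDF) sequence
#'
#' Interleaved beam-on and beam-off frames. Each beam frame carries its own
#' output factor; dark frames contain the dark offset, readout noise and a
#' lag fraction of the previous frame. Frames are returned as a list of
#' (beam, dark) pairs of [raw_image()]s.
#'
#' @param psm_true a [psm()] or matrix.
#' @param beam a [beam_model()].
#' @param geom a [panel_geometry()].
#' @param n_pairs number of beam/dark pairs (>= 1).
#' @param mu_per_frame monitor units per beam-on frame.
#' @param field_x,field_y field at isocenter, cm.
#' @param noise an [acquisition_noise()].
#' @param seed integer seed.
#' @param initial_residual optional matrix of residual signal carried over
#'   from a previous irradiation field; it is added to every frame and decays
#'   by `residual_decay` per frame (the reason early ABDF pairs are
#'   discarded).
#' @param residual_decay per-frame retention factor of the carried residual.
#' @return list of `n_pairs` elements, each `list(beam=, dark=)`.
#' @export
simulate_abdf_sequence <- function(psm_true, beam, geom, n_pairs = 100L,
                                   mu_per_frame = 2,
                                   field_x = 40, field_y = 40,
                                   noise = noiseless(), seed = 1L,
                                   initial_residual = NULL,
                                   residual_decay = 0.9) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be at least 1")
  pv <- if (inherits(psm_true, "psm")) psm_true$values else as.matrix(psm_true)
  br <- beam_response_truth(beam, geom, field_x, field_y)$values
  scale <- mu_per_frame * (geom$sid_ref / geom$sid)^2
  base <- scale * pv * br
  set.seed(seed)
  rd <- function() if (noise$readout_noise_sd > 0)
    noise$readout_noise_sd * scale *
      matrix(stats::rnorm(length(base)), nrow(base), ncol(base))
    else 0
  prev <- matrix(0, nrow(base), ncol(base))
  resid <- if (is.null(initial_residual)) NULL else as.matrix(initial_residual)
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    o <- if (noise$output_fluctuation_sd > 0)
      1 + noise$output_fluctuation_sd * stats::rnorm(1) else 1
    bframe <- o * base + noise$dark_offset +
      noise$lag_fraction * prev + rd()
    if (!is.null(resid)) { bframe <- bframe + resid; resid <- resid * residual_decay }
    prev <- bframe
    dframe <- noise$dark_offset + noise$lag_fraction * prev + rd()
    if (!is.null(resid)) { dframe <- dframe + resid; resid <- resid * residual_decay }
    prev <- dframe
    out[[k]] <- list(
      beam = raw_image(pmax(bframe, 0), geom, mu = mu_per_frame,
                       field_x = field_x, field_y = field_y, kind = "beam"),
      dark = raw_image(pmax(dframe, 0), geom, mu = 0,
                       field_x = field_x, field_y = field_y, kind = "dark"))
  }
  out
}
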