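# Panel/beam coordinate model, multiplicative decomposition and normalization
# conventions shared by every PSM method.
#
# Conventions (used throughout the package):
#   * matrices are indexed [row, col], 1-based; row 1 is the panel edge on the
#     negative-y (longitudinal -) side, column 1 the negative-x (lateral -) edge;
#   * all images live on the isocenter-projected grid: `pitch_iso` is the pixel
#     pitch projected to the isocenter plane at the reference SID, and the SID
#     enters only through magnification / inverse-square scaling;
#   * the beam axis is at x = y = 0 in the isocenter frame; panel shifts are
#     expressed in that frame, so a pixel's beam-frame off-axis position is
#     (panel offset) * (sid_ref/sid) + shift.

#' Panel geometry
#'
#' Describes an EPID panel: grid size, pixel pitch at the isocenter plane,
#' source-to-imager distance (SID) and the panel translation state. The
#' default is the desk-scale 238 x 238 grid spanning the same 40 cm active
#' width as the clinical 1190 x 1190 dosimetry-mode panel.
#'
#' @param n_rows,n_cols integer grid dimensions (>= 2).
#' @param pitch_iso pixel pitch in cm, projected to the isocenter plane at
#'   `sid_ref`.
#' @param sid source-to-imager distance in cm.
#' @param shift_x,shift_y panel translation in cm, expressed in the isocenter
#'   plane (beam frame); positive x is lateral +, positive y longitudinal +.
#' @param sid_ref reference SID in cm used for magnification and
#'   inverse-square scaling.
#' @return an object of class `panel_geometry`.
#' @export
panel_geometry <- function(n_rows = 238L, n_cols = 238L, pitch_iso = 0.168,
                           sid = 100, shift_x = 0, shift_y = 0, sid_ref = 100) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L) stop("panel grid must be at least 2 x 2")
  if (pitch_iso <= 0) stop("pitch_iso must be positive")
  if (sid <= 0 || sid_ref <= 0) stop("sid and sid_ref must be positive")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch_iso = pitch_iso,
                 sid = sid, shift_x = shift_x, shift_y = shift_y,
                 sid_ref = sid_ref),
            class = "panel_geometry")
}

#' @export
print.panel_geometry <- function(x, ...) {
  cat(sprintf("EPID panel: %d x %d px, pitch %.4f cm at isocenter (%.1f x %.1f cm)\n",
              x$n_rows, x$n_cols, x$pitch_iso,
              x$n_rows * x$pitch_iso, x$n_cols * x$pitch_iso))
  cat(sprintf("  SID %.1f cm (ref %.1f), shift (%+.3f, %+.3f) cm\n",
              x$sid, x$sid_ref, x$shift_x, x$shift_y))
  invisible(x)
}

#' Pixel index to beam-frame off-axis position
#'
#' Maps 1-based pixel indices to off-axis coordinates (cm) in the beam frame
#' at the isocenter plane. With zero shifts and `sid == sid_ref` the beam axis
#' falls between the two central pixels of an even grid.
#'
#' @param geom a [panel_geometry()].
#' @param row,col 1-based pixel indices (vectorised).
#' @return list with numeric `x` and `y` in cm.
#' @export
pixel_to_offaxis <- function(geom, row, col) {
  if (any(row < 1L) || any(row > geom$n_rows) ||
      any(col < 1L) || any(col > geom$n_cols))
    stop("pixel index out of range")
  mag <- geom$sid_ref / geom$sid
  list(x = (col - 1 - (geom$n_cols - 1) / 2) * geom$pitch_iso * mag + geom$shift_x,
       y = (row - 1 - (geom$n_rows - 1) / 2) * geom$pitch_iso * mag + geom$shift_y)
}

#' Off-axis coordinate axes for a whole panel
#'
#' @param geom a [panel_geometry()].
#' @return list with `x` (length `n_cols`) and `y` (length `n_rows`), the
#'   beam-frame coordinates of every column / row centre.
#' @export
offaxis_grid <- function(geom) {
  mag <- geom$sid_ref / geom$sid
  list(x = (seq_len(geom$n_cols) - 1 - (geom$n_cols - 1) / 2) *
         geom$pitch_iso * mag + geom$shift_x,
       y = (seq_len(geom$n_rows) - 1 - (geom$n_rows - 1) / 2) *
         geom$pitch_iso * mag + geom$shift_y)
}

#' Raw portal image
#'
#' A non-flood-field-corrected EPID image together with its acquisition
#' metadata. `kind` distinguishes beam-on frames, dark (beam-off) frames and
#' net (dark-subtracted) images.
#'
#' @param pixels numeric matrix of non-negative counts,
#'   `n_rows x n_cols` as given by `geometry`.
#' @param geometry a [panel_geometry()].
#' @param mu monitor units delivered (0 for dark frames).
#' @param field_x,field_y collimated field size at isocenter, cm.
#' @param kind one of "beam", "dark", "net".
#' @return an object of class `raw_image`.
#' @export
raw_image <- function(pixels, geometry, mu, field_x, field_y,
                      kind = c("beam", "dark", "net")) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != geometry$n_rows || ncol(pixels) != geometry$n_cols)
    stop("pixel array shape does not match geometry")
  if (mu < 0) stop("mu must be non-negative")
  if (kind == "dark" && mu != 0) stop("dark frames must have mu = 0")
  structure(list(pixels = pixels, geometry = geometry, mu = mu,
                 field_x = field_x, field_y = field_y, kind = kind),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("raw_image [%s]: %d x %d px, %.1f MU, field %.1f x %.1f cm, SID %.1f, shift (%+.3f, %+.3f)\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$mu,
              x$field_x, x$field_y, x$geometry$sid,
              x$geometry$shift_x, x$geometry$shift_y))
  invisible(x)
}

#' Pixel-sensitivity map
#'
#' The multiplicative per-pixel gain of the imager: what a perfectly uniform
#' beam would record, up to normalization. `valid_mask` marks pixels where the
#' producing method actually constrained the value.
#'
#' @param values numeric matrix of per-pixel gains (>= 0).
#' @param valid_mask logical matrix, same shape; TRUE where constrained.
#' @param normalization "raw" or "central_roi".
#' @return an object of class `psm`.
#' @export
psm <- function(values, valid_mask = NULL,
                normalization = c("raw", "central_roi")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("PSM values must be non-negative")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!identical(dim(valid_mask), dim(values)))
    stop("valid_mask shape does not match values")
  structure(list(values = values, valid_mask = valid_mask,
                 normalization = normalization),
            class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("pixel-sensitivity map: %d x %d px, %.1f%% valid, range [%.4f, %.4f] (%s)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$valid_mask), min(v), max(v), x$normalization))
  invisible(x)
}

#' Beam-response map
#'
#' The smooth multiplicative non-uniformity introduced by the incident beam,
#' on the panel grid in the beam frame.
#'
#' @param values numeric matrix.
#' @param normalization "raw" or "central_axis".
#' @param provenance how the map was obtained: a sampled grid, a 2D spline
#'   fit, a radial fit or the simulator's analytic truth.
#' @return an object of class `beam_response`.
#' @export
beam_response <- function(values, normalization = c("raw", "central_axis"),
                          provenance = c("sampled_grid", "spline_fit",
                                         "radial_fit", "simulator_truth")) {
  structure(list(values = as.matrix(values),
                 normalization = match.arg(normalization),
                 provenance = match.arg(provenance)),
            class = "beam_response")
}

# 1-based row/col index ranges of the central m x m block, symmetric about the
# array centre (for even n the block straddles the centre); m is clamped to n
# so small arrays use what they have.
central_block <- function(n, m) {
  m <- min(m, n)
  start <- floor((n - m) / 2) + 1L
  start:(start + m - 1L)
}

#' Normalize a PSM to its central 10 x 10 pixel mean
#'
#' Divides the map by the mean of the central 10 x 10 pixel block (the block
#' symmetric about the array centre). Idempotent and scale invariant.
#'
#' @param x a [psm()] or plain matrix.
#' @return normalized object of the same type.
#' @export
normalize_psm <- function(x) {
  v <- if (inherits(x, "psm")) x$values else as.matrix(x)
  rows <- central_block(nrow(v), 10L)
  cols <- central_block(ncol(v), 10L)
  m <- mean(v[rows, cols])
  if (!is.finite(m) || m <= 0)
    stop("degenerate normalization: central 10 x 10 ROI mean is not positive")
  if (inherits(x, "psm")) {
    x$values <- v / m
    x$normalization <- "central_roi"
    x
  } else v / m
}

#' Normalize a beam-response to its central-axis value
#'
#' The central-axis value on an even grid is the mean of the central 2 x 2
#' pixels. Idempotent.
#'
#' @param x a [beam_response()] or plain matrix.
#' @return normalized object of the same type.
#' @export
normalize_beam_response <- function(x) {
  v <- if (inherits(x, "beam_response")) x$values else as.matrix(x)
  rows <- central_block(nrow(v), if (nrow(v) %% 2L == 0L) 2L else 1L)
  cols <- central_block(ncol(v), if (ncol(v) %% 2L == 0L) 2L else 1L)
  m <- mean(v[rows, cols])
  if (!is.finite(m) || m <= 0)
    stop("degenerate normalization: central-axis value is not positive")
  if (inherits(x, "beam_response")) {
    x$values <- v / m
    x$normalization <- "central_axis"
    x
  } else v / m
}

#' Extract the central crossplane profile
#'
#' Returns the mean of the two central rows of an image against the lateral
#' off-axis coordinate.
#'
#' @param img numeric matrix or [raw_image()].
#' @param geom a [panel_geometry()]; taken from `img` when it is a raw_image.
#' @return data.frame with columns `x` (cm) and `value`.
#' @export
extract_crossplane_profile <- function(img, geom = NULL) {
  if (inherits(img, "raw_image")) {
    if (is.null(geom)) geom <- img$geometry
    img <- img$pixels
  }
  img <- as.matrix(img)
  if (is.null(geom))
    geom <- panel_geometry(nrow(img), ncol(img), pitch_iso = 40 / ncol(img))
  if (nrow(img) != geom$n_rows || ncol(img) != geom$n_cols)
    stop("image shape does not match geometry")
  rows <- central_block(nrow(img), if (nrow(img) %% 2L == 0L) 2L else 1L)
  data.frame(x = offaxis_grid(geom)$x,
             value = colMeans(img[rows, , drop = FALSE]))
}

#' Decompose a raw image into a PSM given a beam-response
#'
#' Divides the raw image pixelwise by the beam-response and renormalizes to
#' the central 10 x 10 ROI. Pixels where the beam-response is non-positive (or
#' below 1e-9 of its central value) are flagged invalid and set to 0.
#'
#' @param raw a [raw_image()] or matrix.
#' @param br a [beam_response()] or matrix, same shape.
#' @return a normalized [psm()].
#' @export
decompose_image <- function(raw, br) {
  rv <- if (inherits(raw, "raw_image")) raw$pixels else as.matrix(raw)
  bv <- if (inherits(br, "beam_response")) br$values else as.matrix(br)
  if (!identical(dim(rv), dim(bv))) stop("raw and beam-response shapes differ")
  rows <- central_block(nrow(bv), if (nrow(bv) %% 2L == 0L) 2L else 1L)
  cols <- central_block(ncol(bv), if (ncol(bv) %% 2L == 0L) 2L else 1L)
  eps <- 1e-9 * mean(bv[rows, cols])
  ok <- is.finite(bv) & bv > eps
  vals <- matrix(0, nrow(rv), ncol(rv))
  vals[ok] <- rv[ok] / bv[ok]
  vals[vals < 0] <- 0
  out <- psm(vals, valid_mask = ok)
  normalize_psm(out)
}

#' Compose a raw signal from a PSM and a beam-response
#'
#' @param p a [psm()] or matrix.
#' @param br a [beam_response()] or matrix, same shape.
#' @return numeric matrix `psm * beam_response`.
#' @export
compose_image <- function(p, br) {
  pv <- if (inherits(p, "psm")) p$values else as.matrix(p)
  bv <- if (inherits(br, "beam_response")) br$values else as.matrix(br)
  if (!identical(dim(pv), dim(bv))) stop("psm and beam-response shapes differ")
  pv * bv
}
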