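# Three-stage method ("Varian"):
#   stage 1 - coarse PSM by recursive propagation from three large fields
#             shifted 50 pixels laterally / longitudinally;
#   stage 2 - low-frequency correction from two images at different SIDs,
#             compared in the beam frame after inverse-square and
#             magnification scaling, the residual modelled as the exponential
#             of a 2D polynomial;
#   stage 3 - final tuning from four images of one small open field placed in
#             the four panel quadrants, each fitted against the four-image
#             geometric mean by a 2D polynomial and feathered together.

#' Configuration of the three-stage method
#'
#' @param stage1_shift chain step in pixels (one lateral and one longitudinal
#'   shifted acquisition plus the centered reference).
#' @param stage1_seed_halfwidth half-width (px) of the propagation seed
#'   region; must be at least `stage1_shift/2` so every residue class of the
#'   chain step is anchored. The default, 1.5x the step, anchors each class
#'   with at least 9 seed pixels, keeping the unidentifiable inter-class
#'   offsets' variance well below the per-pixel texture.
#' @param stage2_sids the two SIDs (cm) of the stage-2 images.
#' @param stage2_poly_degree total degree of the stage-2 correction
#'   polynomial.
#' @param stage3_shift_px panel shift (px) placing the stage-3 field in each
#'   quadrant; the four quadrant centres are at (+-shift, +-shift).
#' @param stage3_field stage-3 open-field size, cm.
#' @param stage3_poly_degree total degree of the stage-3 tuning polynomials.
#' @return an object of class `varian_config`.
#' @export
varian_config <- function(stage1_shift = 50L,
                          stage1_seed_halfwidth = as.integer(round(1.5 * stage1_shift)),
                          stage2_sids = c(115, 175),
                          stage2_poly_degree = 4L,
                          stage3_shift_px = 48L,
                          stage3_field = 18,
                          stage3_poly_degree = 3L) {
  if (stage2_sids[1] == stage2_sids[2])
    stop("stage-2 SIDs must differ")
  structure(list(stage1_shift = as.integer(stage1_shift),
                 stage1_seed_halfwidth = as.integer(stage1_seed_halfwidth),
                 stage2_sids = stage2_sids,
                 stage2_poly_degree = as.integer(stage2_poly_degree),
                 stage3_shift_px = as.integer(stage3_shift_px),
                 stage3_field = stage3_field,
                 stage3_poly_degree = as.integer(stage3_poly_degree)),
            class = "varian_config")
}

# bivariate monomial basis, total degree <= deg; constant term optional
poly_basis_2d <- function(x, y, deg, intercept = FALSE) {
  cols <- list()
  for (d in (if (intercept) 0L else 1L):deg)
    for (i in 0:d)
      cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  do.call(cbind, cols)
}

# bilinear interpolation of matrix `m` whose rows/cols sit at coordinates
# ys/xs (strictly increasing, regular or not); NA outside
bilinear_interp <- function(m, xs, ys, xq, yq) {
  ix <- findInterval(xq, xs, rightmost.closed = TRUE)
  iy <- findInterval(yq, ys, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix < length(xs) & iy >= 1L & iy < length(ys)
  out <- rep(NA_real_, length(xq))
  ix <- pmin(pmax(ix, 1L), length(xs) - 1L)
  iy <- pmin(pmax(iy, 1L), length(ys) - 1L)
  tx <- (xq - xs[ix]) / (xs[ix + 1L] - xs[ix])
  ty <- (yq - ys[iy]) / (ys[iy + 1L] - ys[iy])
  v <- (1 - ty) * ((1 - tx) * m[cbind(iy, ix)] + tx * m[cbind(iy, ix + 1L)]) +
    ty * ((1 - tx) * m[cbind(iy + 1L, ix)] + tx * m[cbind(iy + 1L, ix + 1L)])
  out[ok] <- v[ok]
  out
}

#' Stage 1: coarse PSM by 50-pixel-shift propagation
#'
#' @param images list with `reference`, `lateral`, `longitudinal`: net
#'   large-field images (matrices or [abdf_average()]s) at shifts (0,0),
#'   (0, +step) and (+step, 0) pixels.
#' @param cfg a [varian_config()].
#' @return a normalized [psm()].
#' @export
varian_stage1 <- function(images, cfg = varian_config()) {
  step <- cfg$stage1_shift
  if (2L * cfg$stage1_seed_halfwidth < step)
    stop("seed region smaller than the chain step leaves residue classes unconstrained")
  recursive_sensitivity_propagation(
    images$reference,
    list(list(net = images$lateral, dr = 0L, dc = step),
         list(net = images$longitudinal, dr = step, dc = 0L)),
    seed_halfwidth = cfg$stage1_seed_halfwidth,
    threshold = 0.3)
}

#' Stage 2: low-frequency correction from two SIDs
#'
#' Both images are divided by the current PSM, scaled by the inverse-square
#' factor, and compared on a common beam-frame grid (magnification maps each
#' pixel to a different off-axis position at the two SIDs). The smooth PSM
#' error is modelled as `exp(P)` with `P` a 2D polynomial (no constant term;
#' a constant log-offset between the images is a nuisance absorbed by an
#' intercept and discarded). The fitted error divides the PSM.
#'
#' @param psm_init current [psm()].
#' @param img_a,img_b centered large-field [raw_image()]s at the two SIDs.
#' @param cfg a [varian_config()].
#' @return list with the corrected `psm`, the fitted log-error surface
#'   `log_error` and the RMS log-difference `rms_before` / `rms_after`.
#' @export
varian_stage2 <- function(psm_init, img_a, img_b, cfg = varian_config()) {
  if (img_a$geometry$sid == img_b$geometry$sid)
    stop("stage-2 images must be acquired at different SIDs (no leverage)")
  pv <- psm_init$values
  ok_p <- psm_init$valid_mask & pv > 0
  corr <- function(img) {
    v <- matrix(NA_real_, nrow(pv), ncol(pv))
    v[ok_p] <- img$pixels[ok_p] / pv[ok_p] *
      (img$geometry$sid / img$geometry$sid_ref)^2
    list(v = v, g = offaxis_grid(img$geometry))
  }
  ca <- corr(img_a); cb <- corr(img_b)
  # common beam-frame grid: the coarser image's pixel positions, trimmed to
  # the mutual footprint
  edges <- c(range(ca$g$x), range(ca$g$y), range(cb$g$x), range(cb$g$y))
  lim <- 0.98 * min(abs(edges))
  gq <- cb$g
  xq <- gq$x[abs(gq$x) <= lim]; yq <- gq$y[abs(gq$y) <= lim]
  if (length(xq) * length(yq) < 0.25 * length(pv))
    stop("beam-frame footprint overlap below 25%")
  qx <- rep(xq, each = length(yq)); qy <- rep(yq, times = length(xq))
  va <- bilinear_interp(ca$v, ca$g$x, ca$g$y, qx, qy)
  vb <- bilinear_interp(cb$v, cb$g$x, cb$g$y, qx, qy)
  ok <- is.finite(va) & is.finite(vb) & va > 0 & vb > 0
  ldiff <- log(va[ok]) - log(vb[ok])
  # panel-frame positions (cm) that each beam-frame point maps to
  ua_x <- qx[ok] * img_a$geometry$sid / img_a$geometry$sid_ref
  ua_y <- qy[ok] * img_a$geometry$sid / img_a$geometry$sid_ref
  ub_x <- qx[ok] * img_b$geometry$sid / img_b$geometry$sid_ref
  ub_y <- qy[ok] * img_b$geometry$sid / img_b$geometry$sid_ref
  sc <- max(abs(c(ua_x, ua_y, ub_x, ub_y)))
  # ldiff(x) = -log e(u_a(x)) + log e(u_b(x)) for a PSM error field e, so the
  # design for the coefficients of log e pairs each beam point's two panel
  # positions with signs (b, -a)
  X <- poly_basis_2d(ub_x / sc, ub_y / sc, cfg$stage2_poly_degree) -
    poly_basis_2d(ua_x / sc, ua_y / sc, cfg$stage2_poly_degree)
  X <- cbind(1, X)  # nuisance intercept (global scale difference)
  beta <- qr.coef(qr(X), ldiff)
  beta[is.na(beta)] <- 0
  resid <- ldiff - X %*% beta
  # log-error surface on the panel grid (panel-frame coordinates)
  gp <- panel_frame(img_b$geometry)
  px <- rep(gp$x, each = length(gp$y)); py <- rep(gp$y, times = length(gp$x))
  Pfull <- poly_basis_2d(px / sc, py / sc, cfg$stage2_poly_degree) %*% beta[-1]
  log_error <- matrix(Pfull, nrow(pv), ncol(pv))
  out <- psm_init
  out$values <- pv / exp(log_error)
  out$values[!ok_p] <- pv[!ok_p]
  list(psm = normalize_psm(out), log_error = log_error,
       rms_before = sqrt(mean(ldiff^2)), rms_after = sqrt(mean(resid^2)))
}

#' Stage 3: quadrant tuning
#'
#' Each of the four small-field images (panel shifted so the field sits in
#' one quadrant) is corrected by the current PSM and mapped to the beam
#' frame; the log-ratio of each image to the four-image geometric mean is
#' fitted by a 2D polynomial over the field footprint. The fitted surfaces,
#' mapped back to panel coordinates, divide the PSM regionally with
#' cosine-feathered blending where quadrants meet.
#'
#' @param psm_mid current [psm()].
#' @param quadrant_images list of four [raw_image()]s whose geometries carry
#'   integer-pixel shifts of (+-s, +-s).
#' @param cfg a [varian_config()].
#' @return list with the corrected `psm` and the mutual RMS log-difference
#'   before and after (`rms_before`, `rms_after`).
#' @export
varian_stage3 <- function(psm_mid, quadrant_images, cfg = varian_config()) {
  if (length(quadrant_images) != 4L)
    stop("stage 3 requires exactly four quadrant images")
  pv <- psm_mid$values
  nr <- nrow(pv); nc <- ncol(pv)
  pitch <- quadrant_images[[1]]$geometry$pitch_iso
  shifts <- lapply(quadrant_images, function(img) {
    s <- c(img$geometry$shift_y, img$geometry$shift_x) / pitch
    if (any(abs(s - round(s)) > 1e-6))
      stop("quadrant images must be shifted by whole pixels")
    as.integer(round(s))
  })
  sgn <- vapply(shifts, function(s) paste(sign(s), collapse = ","), "")
  if (length(unique(sgn)) != 4L)
    stop("quadrant centres must lie in four distinct quadrants")
  # beam-frame stack: entry k at beam pixel (i,j) comes from panel pixel
  # (i - dr_k, j - dc_k)
  logc <- lapply(seq_len(4L), function(k) {
    img <- quadrant_images[[k]]; s <- shifts[[k]]
    v <- shift_mat(img$pixels / ifelse(pv > 0, pv, NA), -s[1], -s[2])
    log(ifelse(is.finite(v) & v > 0, v, NA))
  })
  fin <- Reduce(`&`, lapply(logc, is.finite))
  # field footprint: keep pixels clear of the penumbra in every image
  gmean <- Reduce(`+`, lapply(logc, function(m) ifelse(fin, m, 0))) / 4
  med <- stats::median(gmean[fin])
  foot <- fin & gmean > med + log(0.3)
  if (!any(foot)) stop("quadrant images share no usable beam-frame footprint")
  gp <- panel_frame(quadrant_images[[1]]$geometry)
  bx <- rep(gp$x, each = nr); by <- rep(gp$y, times = nc)  # beam-frame coords
  sc <- max(abs(c(gp$x, gp$y)))
  idx <- which(foot)
  Xf <- cbind(1, poly_basis_2d(bx[idx] / sc, by[idx] / sc, cfg$stage3_poly_degree))
  qrX <- qr(Xf)
  surfaces <- lapply(seq_len(4L), function(k) {
    lr <- (logc[[k]] - gmean)[idx]
    beta <- qr.coef(qrX, lr)
    beta[is.na(beta)] <- 0
    beta
  })
  rms_pair <- function(stack) {
    s <- 0; n <- 0
    for (a in 1:3) for (b in (a + 1):4) {
      d <- (stack[[a]] - stack[[b]])[foot]
      s <- s + sum(d^2); n <- n + length(d)
    }
    sqrt(s / n)
  }
  rms_before <- rms_pair(logc)
  # map each fitted surface back to panel coordinates (beam = panel + shift)
  # and blend with cosine feathering across the panel axes
  px <- rep(gp$x, each = nr); py <- rep(gp$y, times = nc)
  feather <- function(t, w = 1) {  # 0 -> 1 smooth step over [-w, w]
    u <- pmin(pmax(t / w, -1), 1)
    0.5 * (1 + sin(pi * u / 2))
  }
  wx <- feather(px); wy <- feather(py)
  corr <- matrix(0, nr, nc)
  for (k in seq_len(4L)) {
    s <- shifts[[k]]
    qx <- (px + s[2] * pitch) / sc; qy <- (py + s[1] * pitch) / sc
    # the intercept is kept: a quadrant-constant PSM error appears exactly as
    # a constant in the log-ratio (per-irradiation output fluctuation also
    # lands there, but is an order of magnitude below the errors this stage
    # corrects)
    Q <- poly_basis_2d(qx, qy, cfg$stage3_poly_degree) %*% surfaces[[k]][-1] +
      surfaces[[k]][1]
    # quadrant weight: right quadrants need shift_x < 0 (field moved left
    # means beam centre lands on +x side of the panel)
    wqx <- if (s[2] < 0) wx else 1 - wx
    wqy <- if (s[1] < 0) wy else 1 - wy
    corr <- corr + matrix(wqx * wqy * Q, nr, nc)
  }
  out <- psm_mid
  ok_p <- psm_mid$valid_mask & pv > 0
  out$values[ok_p] <- pv[ok_p] * exp(corr[ok_p])
  out <- normalize_psm(out)
  logc_after <- lapply(seq_len(4L), function(k) {
    img <- quadrant_images[[k]]; s <- shifts[[k]]
    v <- shift_mat(img$pixels / ifelse(out$values > 0, out$values, NA),
                   -s[1], -s[2])
    log(ifelse(is.finite(v) & v > 0, v, NA))
  })
  list(psm = out, rms_before = rms_before, rms_after = rms_pair(logc_after))
}

#' Full three-stage PSM pipeline
#'
#' @param acq a `varian_acquisition` from [simulate_varian_acquisition()].
#' @param cfg a [varian_config()].
#' @param n_discard leading ABDF pairs to drop in stage 1.
#' @return list of class `varian_fit`: the final normalized `psm` and
#'   per-stage diagnostics.
#' @export
varian_psm <- function(acq, cfg = acq$config, n_discard = 40L) {
  nets <- lapply(acq$stage1, abdf_average, n_discard = n_discard)
  p1 <- varian_stage1(nets, cfg)
  s2 <- varian_stage2(p1, acq$stage2[[1]], acq$stage2[[2]], cfg)
  s3 <- varian_stage3(s2$psm, acq$stage3, cfg)
  structure(list(psm = normalize_psm(s3$psm),
                 stage1_psm = p1,
                 stage2_rms = c(before = s2$rms_before, after = s2$rms_after),
                 stage3_rms = c(before = s3$rms_before, after = s3$rms_after)),
            class = "varian_fit")
}

#' Simulate the full three-stage acquisition set
#'
#' @param psm_true ground-truth [psm()].
#' @param beam a [beam_model()].
#' @param geom centered [panel_geometry()].
#' @param cfg a [varian_config()].
#' @param n_pairs ABDF pairs per stage-1 sequence.
#' @param mu monitor units for the stage-2/3 images.
#' @param noise an [acquisition_noise()].
#' @param seed base seed.
#' @return list of class `varian_acquisition`.
#' @export
simulate_varian_acquisition <- function(psm_true, beam, geom,
                                        cfg = varian_config(),
                                        n_pairs = 100L, mu = 100,
                                        noise = noiseless(), seed = 1L) {
  step <- cfg$stage1_shift
  mk_seq <- function(dr, dc, sub) {
    gk <- geom
    gk$shift_y <- dr * geom$pitch_iso
    gk$shift_x <- dc * geom$pitch_iso
    simulate_abdf_sequence(psm_true, beam, gk, n_pairs = n_pairs,
                           mu_per_frame = 2, field_x = 40, field_y = 40,
                           noise = noise, seed = seed + sub)
  }
  stage1 <- list(reference = mk_seq(0L, 0L, 0L),
                 lateral = mk_seq(0L, step, 10L),
                 longitudinal = mk_seq(step, 0L, 20L))
  stage2 <- lapply(seq_along(cfg$stage2_sids), function(k) {
    gk <- geom
    gk$sid <- cfg$stage2_sids[k]
    render_net_image(psm_true, beam, gk, mu = mu, field_x = 40, field_y = 40,
                     noise = noise, seed = seed + 30L + k)
  })
  s <- cfg$stage3_shift_px
  quads <- list(c(s, s), c(s, -s), c(-s, s), c(-s, -s))
  stage3 <- lapply(seq_along(quads), function(k) {
    gk <- geom
    gk$shift_y <- quads[[k]][1] * geom$pitch_iso
    gk$shift_x <- quads[[k]][2] * geom$pitch_iso
    render_net_image(psm_true, beam, gk, mu = mu,
                     field_x = cfg$stage3_field, field_y = cfg$stage3_field,
                     noise = noise, seed = seed + 40L + k)
  })
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 config = cfg, geometry = geom),
            class = "varian_acquisition")
}
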