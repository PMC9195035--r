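# Small-shift overlapping-field method ("WashU"): ABDF-averaged large fields
# acquired at small integer-pixel panel shifts give pixel-ratio constraints
# (two pixels that saw the same part of the beam differ only by sensitivity);
# a recursive propagation from a central seed region chains those ratios into
# the full PSM.

#' Average an ABDF frame sequence
#'
#' Discards the first `n_discard` pairs (contaminated by residual signal from
#' a previous irradiation) and returns the mean beam frame minus the mean
#' dark frame of the remainder.
#'
#' @param pairs list of `list(beam=, dark=)` [raw_image()] pairs, as produced
#'   by [simulate_abdf_sequence()].
#' @param n_discard number of leading pairs to drop (default 40 of 100).
#' @return object of class `abdf_average` with the net matrix, the geometry
#'   and the pair bookkeeping.
#' @export
abdf_average <- function(pairs, n_discard = 40L) {
  n_pairs <- length(pairs)
  if (n_pairs <= n_discard)
    stop(sprintf("need more than n_discard = %d pairs, got %d", n_discard, n_pairs))
  keep <- (n_discard + 1L):n_pairs
  beam_sum <- Reduce(`+`, lapply(pairs[keep], function(p) p$beam$pixels))
  dark_sum <- Reduce(`+`, lapply(pairs[keep], function(p) p$dark$pixels))
  structure(list(net = (beam_sum - dark_sum) / length(keep),
                 geometry = pairs[[1]]$beam$geometry,
                 field_x = pairs[[1]]$beam$field_x,
                 field_y = pairs[[1]]$beam$field_y,
                 n_used = length(keep), n_discarded = as.integer(n_discard)),
            class = "abdf_average")
}

#' Shift plan for the small-shift method
#'
#' Validates that the requested panel shift is a whole number of pixels (the
#' propagation compares pixels directly, with no resampling) and returns the
#' minimal plan: a centered reference plus one lateral and one longitudinal
#' shifted acquisition.
#'
#' @param shift_mm requested shift in mm.
#' @param geom a [panel_geometry()].
#' @param field field size in cm (37 x 37 by default, held inside the panel
#'   so the imager electronics are never irradiated).
#' @return object of class `washu_plan`: integer pixel shifts per
#'   acquisition and the field size.
#' @export
washu_plan <- function(shift_mm = 4, geom = panel_geometry(), field = 37) {
  shift_cm <- shift_mm / 10
  px <- shift_cm / geom$pitch_iso
  if (abs(px - round(px)) > 1e-6) {
    near <- max(1, round(px)) * geom$pitch_iso
    stop(sprintf(paste0("shift %.3f cm is %.2f pixels at pitch %.4f cm; ",
                        "shifts must be whole pixels (nearest valid shift: %.4f cm)"),
                 shift_cm, px, geom$pitch_iso, near))
  }
  px <- as.integer(round(px))
  structure(list(shifts = list(reference = c(0L, 0L),
                               lateral = c(0L, px),
                               longitudinal = c(px, 0L)),
                 shift_px = px, field = field),
            class = "washu_plan")
}

# result[r, c] <- m[r + dr, c + dc], padded with `fill`
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- (1L + max(0L, dr)):(nr + min(0L, dr))
  src_c <- (1L + max(0L, dc)):(nc + min(0L, dc))
  out[src_r - dr, src_c - dc] <- m[src_r, src_c]
  out
}

# Solve K independent 1-D difference chains. Emat ((m-1) x K) holds the edge
# values V[i] - V[i+1] = E[i]; invalid (NA) edges break a chain. Potentials
# are returned relative to the centre-most node, with validity meaning "no
# broken edge between this node and the anchor".
chain_solve <- function(Emat) {
  m <- nrow(Emat) + 1L
  ok <- is.finite(Emat)
  E0 <- ifelse(ok, Emat, 0)
  revcum <- function(M) apply(M, 2, function(col) rev(cumsum(rev(col))))
  cum <- rbind(revcum(E0), 0)           # cum[i] = sum of edges i..m-1
  bad <- rbind(revcum(!ok + 0L), 0L)    # broken edges at or above node i
  anchor <- as.integer(ceiling(m / 2))
  P <- sweep(cum, 2, cum[anchor, ])
  valid <- sweep(bad, 2, bad[anchor, ], `==`)
  list(P = P, valid = valid)
}

#' Recursive sensitivity propagation from shift constraints
#'
#' For a shifted acquisition with integer pixel shift (dr, dc), pixel (r, c)
#' of the shifted net image and pixel (r + dr, c + dc) of the reference saw
#' the same part of the beam, so
#' `s(r, c) = s(r + dr, c + dc) * shifted(r, c) / reference(r + dr, c + dc)`.
#' Working in the log domain, sensitivities are chained along the
#' longitudinal shift down every column, columns are tied together by the
#' lateral shift with the per-column offset estimated as the mean over all
#' rows that share a constraint (the geometric-mean merge of parallel
#' chains), and the remaining per-residue-class constants are anchored on
#' the seed region's class means (overall seed mean = 1). Pixels outside the
#' mutual field footprint, or cut off from the seed by broken chains (for
#' example beyond a dead-pixel band wider than the shift step), stay
#' unresolved: they get the neutral value 1 and `valid_mask` FALSE.
#'
#' @param reference net reference image (matrix or [abdf_average()]).
#' @param acquisitions list of two `list(net=, dr=, dc=)` entries: one
#'   lateral shift (dr = 0) and one longitudinal shift (dc = 0); `net` a
#'   matrix or [abdf_average()], shifts in integer pixels.
#' @param seed_halfwidth half-width of the central square seed region, px.
#' @param threshold footprint threshold as a fraction of the reference's
#'   central signal; pixels below it carry no usable constraint.
#' @return a normalized [psm()].
#' @export
recursive_sensitivity_propagation <- function(reference, acquisitions,
                                              seed_halfwidth = 10L,
                                              threshold = 0.3) {
  ref <- if (inherits(reference, "abdf_average")) reference$net else as.matrix(reference)
  nr <- nrow(ref); nc <- ncol(ref)
  ctr <- mean(ref[central_block(nr, 2L), central_block(nc, 2L)])
  if (!is.finite(ctr) || ctr <= 0) stop("reference image has no central signal")
  thr <- threshold * ctr
  vref <- is.finite(ref) & ref > thr
  con <- function(a) {
    net <- if (inherits(a$net, "abdf_average")) a$net$net else as.matrix(a$net)
    dr <- as.integer(a$dr); dc <- as.integer(a$dc)
    refs <- shift_mat(ref, dr, dc)
    ok <- is.finite(net) & net > thr & shift_mat(vref, dr, dc, fill = FALSE)
    L <- matrix(NA_real_, nr, nc)
    L[ok] <- log(net[ok]) - log(refs[ok])
    list(L = L, dr = dr, dc = dc)
  }
  cons <- lapply(acquisitions, con)
  ilat <- which(vapply(cons, function(x) x$dr == 0L && x$dc != 0L, TRUE))
  ilong <- which(vapply(cons, function(x) x$dc == 0L && x$dr != 0L, TRUE))
  if (length(ilat) != 1L || length(ilong) != 1L)
    stop("propagation needs exactly one lateral and one longitudinal shift")
  Llat <- cons[[ilat]]$L; dc <- cons[[ilat]]$dc
  Llong <- cons[[ilong]]$L; dr <- cons[[ilong]]$dr
  if (dc < 0L || dr < 0L) stop("shifts must be positive pixel counts")
  seed <- matrix(FALSE, nr, nc)
  seed[central_block(nr, 2L * seed_halfwidth),
       central_block(nc, 2L * seed_halfwidth)] <- TRUE
  seed <- seed & vref
  if (!any(seed)) stop("seed region carries no usable signal")
  logS <- matrix(NA_real_, nr, nc)
  vmask <- matrix(FALSE, nr, nc)
  P <- matrix(NA_real_, nr, nc)
  Pok <- matrix(FALSE, nr, nc)
  # pass 1: longitudinal chains down every column, per row-residue class
  for (rho in seq_len(dr)) {
    rows <- seq(rho, nr, by = dr)
    m <- length(rows)
    if (m < 2L) next
    sol <- chain_solve(Llong[rows[-m], , drop = FALSE])
    P[rows, ] <- sol$P
    Pok[rows, ] <- sol$valid
  }
  # pass 2: lateral tying of column offsets, per row-residue class
  for (rho in seq_len(dr)) {
    rows <- seq(rho, nr, by = dr)
    # offset difference between column c and c+dc for this class:
    # mean over rows of (Llat - P[r,c] + P[r,c+dc]) where everything holds
    D <- matrix(NA_real_, 1, nc)
    num <- Llat[rows, , drop = FALSE] - P[rows, , drop = FALSE] +
      shift_mat(P[rows, , drop = FALSE], 0L, dc)
    usable <- is.finite(num) & Pok[rows, , drop = FALSE] &
      shift_mat(Pok[rows, , drop = FALSE], 0L, dc, fill = FALSE)
    num[!usable] <- NA_real_
    D <- colMeans(num, na.rm = TRUE)
    D[colSums(usable) == 0L] <- NA_real_
    for (sig in seq_len(dc)) {
      cols <- seq(sig, nc, by = dc)
      K <- length(cols)
      if (K < 2L) next
      sol <- chain_solve(matrix(D[cols[-K]], ncol = 1))
      A <- drop(sol$P); Aok <- drop(sol$valid)
      sub <- logS[rows, cols, drop = FALSE]
      sub <- P[rows, cols, drop = FALSE] +
        matrix(A, length(rows), K, byrow = TRUE)
      okm <- Pok[rows, cols, drop = FALSE] &
        matrix(Aok, length(rows), K, byrow = TRUE)
      # anchor the residue-class constant on the seed class mean
      sd_sel <- seed[rows, cols, drop = FALSE] & okm
      if (!any(sd_sel)) { okm[] <- FALSE } else {
        sub <- sub - mean(sub[sd_sel])
      }
      logS[rows, cols] <- sub
      vmask[rows, cols] <- okm
    }
  }
  vmask <- vmask & vref & is.finite(logS)
  n_masked <- sum(vref & !vmask)
  if (n_masked > 0)
    warning(sprintf("%d in-footprint pixels unreachable from the seed region; masked",
                    n_masked))
  if (!any(vmask)) stop("no pixel could be anchored to the seed region")
  logS <- logS - mean(logS[seed & vmask])
  vals <- matrix(1, nr, nc)
  vals[vmask] <- exp(logS[vmask])
  normalize_psm(psm(vals, valid_mask = vmask))
}

#' Full small-shift PSM pipeline
#'
#' ABDF-averages each shifted sequence and propagates the pixel-ratio
#' constraints into a full PSM.
#'
#' @param acq a `washu_acquisition` from [simulate_washu_acquisition()], or a
#'   list with `reference` and shifted entries of ABDF pair lists plus
#'   `shift_px` metadata.
#' @param n_discard leading ABDF pairs to drop.
#' @param seed_halfwidth,threshold see
#'   [recursive_sensitivity_propagation()].
#' @return a normalized [psm()].
#' @export
washu_psm <- function(acq, n_discard = 40L, seed_halfwidth = 10L,
                      threshold = 0.3) {
  ref <- abdf_average(acq$sequences$reference$pairs, n_discard)
  shifted <- lapply(acq$sequences[names(acq$sequences) != "reference"],
                    function(s) list(net = abdf_average(s$pairs, n_discard),
                                     dr = s$shift_px[1], dc = s$shift_px[2]))
  recursive_sensitivity_propagation(ref, shifted,
                                    seed_halfwidth = seed_halfwidth,
                                    threshold = threshold)
}

#' Simulate a small-shift ABDF acquisition set
#'
#' One ABDF sequence per planned shift. Each sequence starts with a residual
#' signal from a preceding open-field irradiation, which the discard phase of
#' [abdf_average()] must remove.
#'
#' @param psm_true ground-truth [psm()].
#' @param beam a [beam_model()].
#' @param geom centered [panel_geometry()].
#' @param plan a [washu_plan()].
#' @param n_pairs ABDF pairs per sequence.
#' @param mu_per_frame monitor units per beam-on frame.
#' @param noise an [acquisition_noise()].
#' @param residual_fraction initial carried-over signal as a fraction of the
#'   open-field frame signal.
#' @param seed base seed.
#' @return list of class `washu_acquisition`.
#' @export
simulate_washu_acquisition <- function(psm_true, beam, geom,
                                       plan = washu_plan(geom = geom),
                                       n_pairs = 100L, mu_per_frame = 2,
                                       noise = noiseless(),
                                       residual_fraction = 0.2,
                                       seed = 1L) {
  pv <- if (inherits(psm_true, "psm")) psm_true$values else as.matrix(psm_true)
  resid <- residual_fraction * mu_per_frame *
    beam_response_truth(beam, geom, 40, 40)$values * pv
  seqs <- list()
  k <- 0L
  for (nm in names(plan$shifts)) {
    sh <- plan$shifts[[nm]]
    gk <- geom
    gk$shift_y <- sh[1] * geom$pitch_iso
    gk$shift_x <- sh[2] * geom$pitch_iso
    seqs[[nm]] <- list(
      pairs = simulate_abdf_sequence(psm_true, beam, gk, n_pairs = n_pairs,
                                     mu_per_frame = mu_per_frame,
                                     field_x = plan$field, field_y = plan$field,
                                     noise = noise, seed = seed + 100L * k,
                                     initial_residual = resid),
      shift_px = sh)
    k <- k + 1L
  }
  structure(list(sequences = seqs, plan = plan, geometry = geom),
            class = "washu_acquisition")
}
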