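# Cubic spline interpolation with not-a-knot end conditions, plus the
# tensor-product 2D beam-response fit built on it. Outside the sampled
# rectangle the interpolant is continued linearly along each axis using the
# boundary value and gradient of the spline.

#' Not-a-knot cubic spline interpolation
#'
#' Fits the interpolating cubic spline through (x, y) with not-a-knot end
#' conditions: the third derivative is continuous across the second and the
#' second-to-last knot, so the two end intervals share one cubic with their
#' neighbours. Reproduces any single cubic polynomial exactly. Requires at
#' least 4 points.
#'
#' @param x strictly increasing knot positions.
#' @param y values at the knots.
#' @return an object of class `nak_spline`.
#' @export
nak_spline <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4L) stop("not-a-knot spline needs at least 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  h <- diff(x)
  # unknowns: second derivatives M_1..M_n
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  # not-a-knot: continuity of the third derivative at x_2 and x_{n-1}
  A[1, 1] <- h[2]; A[1, 2] <- -(h[1] + h[2]); A[1, 3] <- h[1]
  A[n, n - 2] <- h[n - 1]; A[n, n - 1] <- -(h[n - 2] + h[n - 1]); A[n, n] <- h[n - 2]
  M <- solve(A, b)
  structure(list(x = x, y = y, M = M, h = h), class = "nak_spline")
}

#' Evaluate a not-a-knot spline with linear extrapolation
#'
#' Inside the knot range the spline is evaluated exactly; outside, the curve
#' is continued linearly with the boundary value and first derivative.
#'
#' @param object a [nak_spline()].
#' @param xout evaluation positions.
#' @param ... unused.
#' @return numeric vector of values.
#' @export
predict.nak_spline <- function(object, xout, ...) {
  x <- object$x; y <- object$y; M <- object$M; h <- object$h
  n <- length(x)
  eval_in <- function(t) {
    i <- pmin(pmax(findInterval(t, x), 1L), n - 1L)
    d1 <- t - x[i]; d2 <- x[i + 1] - t
    (M[i] * d2^3 + M[i + 1] * d1^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * d2 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * d1
  }
  deriv_at <- function(t) {
    i <- pmin(pmax(findInterval(t, x), 1L), n - 1L)
    d1 <- t - x[i]; d2 <- x[i + 1] - t
    (-M[i] * d2^2 + M[i + 1] * d1^2) / (2 * h[i]) +
      (y[i + 1] - y[i]) / h[i] - (M[i + 1] - M[i]) * h[i] / 6
  }
  out <- numeric(length(xout))
  lo <- xout < x[1]; hi <- xout > x[n]; mid <- !(lo | hi)
  if (any(mid)) out[mid] <- eval_in(xout[mid])
  if (any(lo)) out[lo] <- y[1] + deriv_at(x[1]) * (xout[lo] - x[1])
  if (any(hi)) out[hi] <- y[n] + deriv_at(x[n]) * (xout[hi] - x[n])
  out
}

#' Fit a 2D beam-response by tensor-product not-a-knot splines
#'
#' Interpolates beam-response samples on a full rectangular grid of off-axis
#' points with a tensor-product not-a-knot cubic spline and evaluates it on
#' the whole panel, continuing linearly (boundary gradient of the spline)
#' outside the sampled rectangle; corner regions apply the x-extension then
#' the y-extension.
#'
#' @param samples a `sampled_beam_response` (see [beam_response_samples()])
#'   or a list with `x`, `y`, and a `length(y) x length(x)` matrix `values`.
#' @param geom a [panel_geometry()] describing the evaluation grid.
#' @return a [beam_response()] with provenance `"spline_fit"`, normalized to
#'   central axis.
#' @export
fit_beam_response_2d <- function(samples, geom) {
  xs <- samples$x; ys <- samples$y
  vals <- samples$values
  if (!is.matrix(vals) || nrow(vals) != length(ys) || ncol(vals) != length(xs))
    stop("samples must form a full rectangular grid (values: length(y) x length(x))")
  if (length(xs) < 4L || length(ys) < 4L)
    stop("not-a-knot interpolation needs at least 4 points along each axis")
  g <- offaxis_grid(geom)
  # pass 1: spline along x for every sampled row
  stage <- matrix(NA_real_, length(ys), geom$n_cols)
  for (j in seq_along(ys))
    stage[j, ] <- predict(nak_spline(xs, vals[j, ]), g$x)
  # pass 2: spline along y for every panel column
  out <- matrix(NA_real_, geom$n_rows, geom$n_cols)
  for (c in seq_len(geom$n_cols))
    out[, c] <- predict(nak_spline(ys, stage[, c]), g$y)
  normalize_beam_response(beam_response(out, provenance = "spline_fit"))
}
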