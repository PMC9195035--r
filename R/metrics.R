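# Comparison surface: per-pixel percentage deviation maps and histograms,
# summary statistics, repeatability (per-pixel coefficient of variation)
# maps and recovery reports against a known truth.

#' Per-pixel percentage deviation map
#'
#' `100 * (a - b) / b`, NA wherever either input is invalid or the reference
#' is zero.
#'
#' @param a,b [psm()]s (or matrices), same shape, both normalized the same
#'   way.
#' @return numeric matrix of percentages with NA at invalid pixels.
#' @export
percent_deviation_map <- function(a, b) {
  av <- if (inherits(a, "psm")) a$values else as.matrix(a)
  bv <- if (inherits(b, "psm")) b$values else as.matrix(b)
  if (!identical(dim(av), dim(bv))) stop("shapes differ")
  ok <- bv != 0
  if (inherits(a, "psm")) ok <- ok & a$valid_mask
  if (inherits(b, "psm")) ok <- ok & b$valid_mask
  out <- matrix(NA_real_, nrow(av), ncol(av))
  out[ok] <- 100 * (av[ok] - bv[ok]) / bv[ok]
  out
}

#' Summary statistics of a percentage deviation map
#'
#' @param map matrix of percentages (NA = invalid).
#' @param bin_width histogram bin width in percent.
#' @return object of class `deviation_stats`: mean, median, sd (sample,
#'   n-1), `p95_abs` (95th percentile of |deviation|), the histogram and the
#'   valid / masked pixel counts.
#' @export
deviation_stats <- function(map, bin_width = 0.05) {
  v <- map[is.finite(map)]
  if (!length(v)) stop("deviation map has no valid pixels")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(mean = mean(v), median = stats::median(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 p95_abs = unname(stats::quantile(abs(v), 0.95)),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 n_pixels = length(v),
                 n_masked = sum(!is.finite(map))),
            class = "deviation_stats")
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf("deviation over %d px (%d masked): mean %+.3f%%, median %+.3f%%, SD %.3f%%, p95|dev| %.3f%%\n",
              x$n_pixels, x$n_masked, x$mean, x$median, x$sd, x$p95_abs))
  invisible(x)
}

#' Per-pixel repeatability map
#'
#' For repeated determinations of a PSM, `100 * SD / mean` per pixel (sample
#' SD, n-1 divisor). Pixels invalid in any repeat are NA.
#'
#' @param psm_list list of >= 2 [psm()]s, each normalized.
#' @return object of class `repeatability_map`: the map plus its median and
#'   95th percentile over valid pixels (the "95% of pixels repeatable to
#'   within" statistic).
#' @export
repeatability_map <- function(psm_list) {
  if (length(psm_list) < 2L) stop("repeatability needs at least 2 repeats")
  vals <- lapply(psm_list, function(p) if (inherits(p, "psm")) p$values else as.matrix(p))
  ok <- Reduce(`&`, lapply(psm_list, function(p)
    if (inherits(p, "psm")) p$valid_mask else is.finite(as.matrix(p))))
  n <- length(vals)
  s <- Reduce(`+`, vals)
  s2 <- Reduce(`+`, lapply(vals, function(v) v^2))
  mu <- s / n
  sd <- sqrt(pmax(s2 - n * mu^2, 0) / (n - 1))
  out <- matrix(NA_real_, nrow(mu), ncol(mu))
  use <- ok & mu > 0
  out[use] <- 100 * sd[use] / mu[use]
  v <- out[is.finite(out)]
  structure(list(values = out, n_repeats = n,
                 median = stats::median(v),
                 p95 = unname(stats::quantile(v, 0.95))),
            class = "repeatability_map")
}

#' @export
print.repeatability_map <- function(x, ...) {
  cat(sprintf("repeatability (n = %d): median %.3f%%, 95%% of pixels within %.3f%% (1 SD)\n",
              x$n_repeats, x$median, x$p95))
  invisible(x)
}

#' Recovery report against a known truth
#'
#' Deviation statistics of an estimated PSM against the simulator truth,
#' overall and in concentric radial bands (centre 0-10 cm, mid 10-15 cm,
#' edge 15-20 cm), where the shifted-field and small-shift methods are
#' expected to degrade.
#'
#' @param psm_est estimated [psm()].
#' @param psm_true ground-truth [psm()].
#' @param geom a [panel_geometry()] for the radial bands.
#' @param bands band edges in cm.
#' @return object of class `recovery_report`: overall `stats`, per-band
#'   stats, and the deviation map.
#' @export
recovery_report <- function(psm_est, psm_true, geom = NULL,
                            bands = c(0, 10, 15, 20)) {
  dev <- percent_deviation_map(psm_est, psm_true)
  if (is.null(geom))
    geom <- panel_geometry(nrow(dev), ncol(dev), pitch_iso = 40 / ncol(dev))
  g <- panel_frame(geom)
  r <- sqrt(outer(g$y^2, g$x^2, "+"))
  band_stats <- lapply(seq_len(length(bands) - 1L), function(k) {
    sel <- r >= bands[k] & r < bands[k + 1L] & is.finite(dev)
    if (!any(sel)) return(NULL)
    st <- deviation_stats(ifelse(sel, dev, NA_real_))
    st$median_abs <- stats::median(abs(dev[sel]))
    st
  })
  names(band_stats) <- paste0(bands[-length(bands)], "-", bands[-1], "cm")
  overall <- deviation_stats(dev)
  overall$median_abs <- median_abs_dev(dev)
  structure(list(stats = overall, bands = band_stats, map = dev),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("overall: "); print(x$stats)
  for (nm in names(x$bands)) if (!is.null(x$bands[[nm]])) {
    cat(sprintf("  %-9s median |dev| %.4f%%, SD %.3f%%\n", nm,
                x$bands[[nm]]$median_abs, x$bands[[nm]]$sd))
  }
  invisible(x)
}

#' Median absolute percentage deviation of a map
#'
#' @param map a deviation map (matrix of percentages, NA = invalid).
#' @return scalar, percent.
#' @export
median_abs_dev <- function(map) stats::median(abs(map[is.finite(map)]))
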