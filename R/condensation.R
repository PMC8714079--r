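#' Condensation-parameter configuration
#'
#' The condensation parameter summarizes the pixel-value distribution inside
#' a fixed square ROI centred on the paternal pronucleus: after min-max
#' rescaling of the ROI to `[0, rescale_max]`, it is the fraction of pixels
#' strictly below `threshold_fraction * rescale_max`. With the defaults
#' (fraction 0.4 of a 255 maximum) the cut-off is 102. As chromatin compacts
#' into a few bright foci over dark nucleoplasm, more pixels fall below the
#' cut-off and the parameter rises toward 1.
#'
#' @param roi_size_px side of the square ROI, pixels (odd, default 21).
#' @param threshold_fraction fraction of the rescaled maximum (default 0.4).
#' @param rescale_max top of the rescaled range (default 255).
#' @param span loess span used for display smoothing (default 0.4).
#' @param dt_s frame interval, seconds (default 10).
#' @return object of class `"condensation_config"` with the derived
#'   `threshold` (`threshold_fraction * rescale_max`).
#' @export
condensation_config <- function(roi_size_px = 21L, threshold_fraction = 0.4,
                                rescale_max = 255, span = 0.4, dt_s = 10) {
  if (!is_count(roi_size_px) || roi_size_px < 3L || roi_size_px %% 2L == 0L)
    stopf("roi_size_px must be an odd integer >= 3 (centrable)")
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stopf("threshold_fraction must lie in (0, 1)")
  if (rescale_max <= 0) stopf("rescale_max must be > 0")
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  if (dt_s <= 0) stopf("dt_s must be > 0")
  structure(list(roi_size_px = as.integer(roi_size_px),
                 threshold_fraction = threshold_fraction,
                 rescale_max = rescale_max,
                 threshold = threshold_fraction * rescale_max,
                 span = span, dt_s = dt_s),
            class = "condensation_config")
}

#' Locate the pronucleus in a frame
#'
#' Segmentation path used to centre the condensation ROI: contrast stretch,
#' circular mean filter (2 px radius), Otsu threshold, then the centroid of
#' the connected component nearest `seed_point` (or the largest component
#' when no seed is given), rounded to the nearest pixel. The filtered copy
#' is used only here — the condensation statistic itself always reads the
#' unfiltered projection.
#'
#' @param frame image frame (max projection).
#' @param seed_point optional `c(x, y)`.
#' @return `c(x, y)` integer pixel coordinates of the pronucleus centre.
#' @export
locate_pronucleus <- function(frame, seed_point = NULL) {
  frame <- image_frame(frame)
  if (max(frame) == min(frame))
    stopf("no foreground: frame is constant, cannot segment a pronucleus")
  seg <- mean_filter(contrast_stretch(frame), 2)
  th <- otsu_threshold(build_histogram(seg))
  mask <- apply_threshold(seg, th)
  if (!any(mask)) stopf("no foreground: threshold removed every pixel")
  lab <- label_components(mask, 8L)
  cent <- component_centroids(lab)
  pick <- if (is.null(seed_point)) {
    which.max(tabulate(lab[lab > 0L], nbins = max(lab)))
  } else {
    which.min((cent[, "x"] - seed_point[1L])^2 + (cent[, "y"] - seed_point[2L])^2)
  }
  c(x = as.integer(round(cent[pick, "x"])), y = as.integer(round(cent[pick, "y"])))
}

#' Condensation parameter of one ROI
#'
#' Min-max rescales the ROI pixel values to `[0, rescale_max]` and returns
#' the fraction strictly below the configured cut-off. The rescaling makes
#' the statistic invariant under any positive affine transform of the raw
#' intensities, which removes photobleaching and gain differences between
#' recordings. A constant ROI (no contrast at all: the diffuse limit)
#' returns 0 by convention.
#'
#' @param roi_pixels numeric vector of ROI pixel values (>= 2 pixels).
#' @param config a [condensation_config()].
#' @return fraction in `[0, 1]`.
#' @export
condensation_parameter <- function(roi_pixels, config = condensation_config()) {
  v <- as.numeric(roi_pixels)
  if (length(v) < 2L) stopf("condensation ROI must contain at least 2 pixels")
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(0)
  rescaled <- (v - lo) / (hi - lo) * config$rescale_max
  mean(rescaled < config$threshold)
}

#' Condensation time course for one embryo
#'
#' Runs the per-frame measurement over a series: each timepoint is
#' max-projected; the pronucleus is located on a filtered segmentation copy
#' ([locate_pronucleus()]); a square ROI of `roi_size_px` is centred there
#' (clamped to stay inside the frame) on the *unfiltered* projection; and
#' the condensation parameter is computed. Times are reported in seconds
#' relative to nuclear envelope breakdown (negative before NEB). If the
#' pronucleus cannot be segmented in a frame, the previous centre is carried
#' forward (with a message) for at most 2 consecutive frames; longer losses
#' are an error.
#'
#' @param series an [image_series()].
#' @param neb_frame 1-based NEB frame index.
#' @param seed_point `c(x, y)` near the paternal pronucleus in frame 1.
#' @param config a [condensation_config()].
#' @param embryo_id identifier carried into the result.
#' @return object of class `"condensation_curve"`: `times_s`, `values`,
#'   `centres`, `neb_frame`, `embryo_id`.
#' @export
condensation_timecourse <- function(series, neb_frame, seed_point = NULL,
                                    config = condensation_config(),
                                    embryo_id = NA) {
  nt <- n_frames(series)
  if (!is_count(neb_frame) || neb_frame < 1L || neb_frame > nt)
    stopf("neb_frame must be a frame index within the series (1..%d)", nt)
  half <- (config$roi_size_px - 1L) %/% 2L
  values <- numeric(nt)
  centres <- matrix(NA_integer_, nt, 2L, dimnames = list(NULL, c("x", "y")))
  prev <- seed_point
  lost <- 0L
  for (t in seq_len(nt)) {
    frame <- project_timepoint(series, t, max_project)
    ctr <- tryCatch(locate_pronucleus(frame, prev), error = function(e) NULL)
    if (is.null(ctr)) {
      lost <- lost + 1L
      if (lost > 2L || is.null(prev))
        stopf("pronucleus lost at frame %d (%d consecutive frames)", t, lost)
      message(sprintf("frame %d: pronucleus not found, carrying centre forward", t))
      ctr <- c(x = prev[[1L]], y = prev[[2L]])
    } else {
      lost <- 0L
    }
    dm <- dim(frame)
    cx <- min(max(ctr[[1L]], half + 1L), dm[2L] - half)
    cy <- min(max(ctr[[2L]], half + 1L), dm[1L] - half)
    roi <- roi_rect(cx - half, cy - half, config$roi_size_px, config$roi_size_px)
    values[t] <- condensation_parameter(roi_pixels(frame, roi), config)
    centres[t, ] <- c(cx, cy)
    prev <- c(cx, cy)
  }
  structure(list(embryo_id = embryo_id,
                 times_s = (seq_len(nt) - neb_frame) * series$dt_s,
                 values = values, centres = centres,
                 neb_frame = as.integer(neb_frame), dt_s = series$dt_s),
            class = "condensation_curve")
}

#' @export
print.condensation_curve <- function(x, ...) {
  cat(sprintf("<condensation_curve> embryo %s: %d timepoints, t = %g..%g s rel. NEB\n",
              format(x$embryo_id), length(x$values),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' @export
as.data.frame.condensation_curve <- function(x, ...) {
  data.frame(embryo_id = x$embryo_id, time_s = x$times_s, parameter = x$values)
}

#' Aggregate condensation curves across embryos
#'
#' Aligns curves on their NEB-relative time axis and reports, per timepoint,
#' the mean, sample standard deviation and number of contributing embryos,
#' plus a loess-smoothed mean for display. Timepoints contributed by a
#' single embryo carry sd 0 with `n = 1` recorded.
#'
#' @param curves list of [condensation_timecourse()] results sharing `dt_s`.
#' @param span smoothing span passed to [loess_smooth()] (default 0.4).
#' @return object of class `"aggregate_curve"`: `times_s`, `mean`, `sd`,
#'   `n`, `smoothed`.
#' @export
aggregate_curves <- function(curves, span = 0.4) {
  if (length(curves) < 1L) stopf("need at least one curve")
  stopifnot(all(vapply(curves, inherits, logical(1), "condensation_curve")))
  dts <- vapply(curves, function(c) c$dt_s, numeric(1))
  if (length(unique(dts)) != 1L) stopf("curves must share the frame interval")
  times <- sort(unique(unlist(lapply(curves, function(c) c$times_s))))
  if (length(times) == 0L) stopf("no overlapping timepoints")
  vals <- lapply(curves, function(c) {
    v <- rep(NA_real_, length(times))
    v[match(c$times_s, times)] <- c$values
    v
  })
  m <- do.call(cbind, vals)
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) 0 else stats::sd(r)
  })
  smoothed <- if (length(times) >= 3L) loess_smooth(times, mu, span) else mu
  structure(list(times_s = times, mean = mu, sd = sdv, n = n,
                 smoothed = smoothed, span = span),
            class = "aggregate_curve")
}

#' @export
as.data.frame.aggregate_curve <- function(x, ...) {
  data.frame(time_s = x$times_s, mean = x$mean, sd = x$sd, n = x$n,
             smoothed = x$smoothed)
}

#' @export
plot.aggregate_curve <- function(x, ..., col = "steelblue",
                                 xlab = "time relative to NEB (s)",
                                 ylab = "condensation parameter") {
  graphics::plot(x$times_s, x$mean, pch = 16, col = col, ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$times_s, rev(x$times_s)),
                    c(pmin(1, x$mean + x$sd), rev(pmax(0, x$mean - x$sd))),
                    col = grDevices::adjustcolor(col, alpha.f = 0.2), border = NA)
  graphics::lines(x$times_s, x$smoothed, col = col, lwd = 2)
  invisible(x)
}

#' Locally weighted (loess-style) smoothing
#'
#' Degree-1 local regression with tricube weights: for each point, a
#' weighted least-squares line is fitted over the `ceiling(span * n)`
#' nearest points, with weights `(1 - (d / d_max)^3)^3`. Exactly reproduces
#' linear data at any span and is used only for display smoothing of
#' aggregate curves.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @param span fraction of points per local window, in (0, 1].
#' @return fitted values at each `x`.
#' @export
loess_smooth <- function(x, y, span = 0.4) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stopf("loess smoothing needs at least 3 points")
  if (span <= 0 || span > 1) stopf("span must lie in (0, 1]")
  k <- max(3L, ceiling(span * n))
  if (k > n) k <- n
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    dmax <- max(d[idx])
    w <- if (dmax == 0) rep(1, k) else (1 - pmin(1, d[idx] / dmax)^3)^3
    w[w < 0] <- 0
    if (sum(w > 0) < 2L) { fitted[i] <- y[i]; next }
    fit <- stats::lm.wfit(cbind(1, x[idx]), y[idx], w)
    cf <- stats::coef(fit)
    fitted[i] <- if (anyNA(cf)) stats::weighted.mean(y[idx], w)
                 else sum(cf * c(1, x[i]))
  }
  fitted
}
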