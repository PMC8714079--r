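#' Intensity histograms
#'
#' Builds the 256-bin (by default) histogram all auto-thresholding in this
#' package operates on. Bin edges span the data minimum to maximum with
#' equal-width, right-open bins (the last bin is closed), so for 8-bit data
#' covering the full 0..255 range the bins coincide with the integer levels.
#' Thresholding on a fixed-bin histogram of the data range reproduces the
#' behaviour of the interactive tool the field uses for these steps and keeps
#' exhaustive threshold search cheap even for 16-bit input.
#'
#' @param x an image frame (numeric matrix) or a numeric vector of ROI pixels.
#' @param n_bins number of bins (default 256).
#' @param range optional `c(lo, hi)` to histogram over a fixed intensity
#'   range instead of the data range.
#' @return object of class `"intensity_histogram"` with `bin_edges` (length
#'   `n_bins + 1`), `counts` and `n_bins`.
#' @export
build_histogram <- function(x, n_bins = 256L, range = NULL) {
  v <- if (is.matrix(x)) as.vector(x) else as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stopf("cannot histogram zero pixels")
  if (!is_count(n_bins) || n_bins < 2L) stopf("n_bins must be an integer >= 2")
  if (is.null(range)) range <- c(min(v), max(v))
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) hi <- lo + 1  # constant data: unit-wide span, all mass in bin 1
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, n_bins = as.integer(n_bins)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%g, %g], %d pixels\n",
              x$n_bins, x$bin_edges[1L], x$bin_edges[x$n_bins + 1L],
              sum(x$counts)))
  invisible(x)
}

check_hist <- function(hist) {
  if (!inherits(hist, "intensity_histogram"))
    stopf("expected an intensity_histogram")
  if (sum(hist$counts > 0L) < 2L)
    stopf("degenerate histogram: fewer than 2 non-empty bins")
  invisible(hist)
}

new_threshold <- function(hist, k, method, criterion) {
  # background = bins 1..k; foreground = bins k+1..B.
  structure(list(index = k - 1L,                       # 0-based top background bin
                 level = hist$bin_edges[k + 1L],       # lower edge of first fg bin
                 k = k, method = method, criterion = criterion,
                 bin_edges = hist$bin_edges, n_bins = hist$n_bins),
            class = "auto_threshold")
}

#' @export
print.auto_threshold <- function(x, ...) {
  cat(sprintf("<auto_threshold> %s: bin index %d, raw level %g\n",
              x$method, x$index, x$level))
  invisible(x)
}

#' Otsu's between-class variance threshold
#'
#' Scans every histogram split and returns the one maximizing the
#' between-class variance \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}; ties are
#' broken toward the smallest split. Pixels falling in bins strictly above
#' the returned split are foreground (see [apply_threshold()]).
#'
#' @param hist an [build_histogram()] result with at least two non-empty bins.
#' @return an `"auto_threshold"` object: `index` is the 0-based highest
#'   background bin, `level` the raw intensity at the background/foreground
#'   boundary.
#' @export
otsu_threshold <- function(hist) {
  check_hist(hist)
  p <- hist$counts / sum(hist$counts)
  B <- hist$n_bins
  lev <- seq_len(B) - 1                    # bin indices as working levels
  w0 <- cumsum(p)
  m <- cumsum(p * lev)
  mt <- m[B]
  k <- seq_len(B - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  num <- (mt * w0[k] - m[k])^2
  sigma_b <- ifelse(valid, num / (w0[k] * (1 - w0[k])), -Inf)
  best <- which(sigma_b == max(sigma_b))[1L]
  new_threshold(hist, best, "otsu", sigma_b[best])
}

#' Maximum-entropy (Kapur-Sahoo-Wong) threshold
#'
#' Returns the split maximizing the sum of the Shannon entropies of the
#' renormalized histogram below and above the split; a side with no mass
#' contributes zero entropy. Ties are broken toward the smallest split.
#'
#' @inheritParams otsu_threshold
#' @return an `"auto_threshold"` object.
#' @export
max_entropy_threshold <- function(hist) {
  check_hist(hist)
  p <- hist$counts / sum(hist$counts)
  B <- hist$n_bins
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)
  S0 <- cumsum(plogp)
  k <- seq_len(B - 1L)
  H0 <- ifelse(P0[k] > 0, log(P0[k]) - S0[k] / P0[k], 0)
  P1 <- 1 - P0[k]
  S1 <- S0[B] - S0[k]
  H1 <- ifelse(P1 > 0, log(P1) - S1 / P1, 0)
  # only splits with mass on both sides are candidates
  crit <- ifelse(P0[k] > 0 & P1 > 0, H0 + H1, -Inf)
  best <- which(crit == max(crit))[1L]
  new_threshold(hist, best, "max_entropy", crit[best])
}

#' Apply an auto-threshold to a frame
#'
#' Classifies pixels by the histogram binning the threshold was computed on:
#' a pixel is foreground when its bin lies strictly above the background
#' bins (for integer data on integer bins this is "value > threshold level").
#'
#' @param frame image frame.
#' @param threshold an `"auto_threshold"` object.
#' @return logical mask, `TRUE` = foreground.
#' @export
apply_threshold <- function(frame, threshold) {
  stopifnot(inherits(threshold, "auto_threshold"))
  frame <- image_frame(frame)
  idx <- findInterval(frame, threshold$bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  m <- matrix(idx > threshold$k, nrow(frame), ncol(frame))
  m
}

#' Circular mean filter
#'
#' Replaces each pixel by the mean over the circular neighbourhood
#' \eqn{\{(dx, dy): dx^2 + dy^2 \le r^2\}}. At image edges the mean is taken
#' over the in-bounds members only, so the filter never invents intensity
#' (output stays within the input min and max). The 2-pixel radius used for
#' segmentation smoothing gives the familiar 13-pixel disc.
#'
#' @param frame image frame.
#' @param radius_px neighbourhood radius in pixels (>= 1).
#' @return filtered frame.
#' @export
mean_filter <- function(frame, radius_px) {
  frame <- image_frame(frame)
  if (!is.numeric(radius_px) || radius_px < 1) stopf("radius must be >= 1")
  r <- radius_px
  off <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  nr <- nrow(frame); nc <- ncol(frame)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    src_r <- max(1L, 1L - dy):min(nr, nr - dy)
    src_c <- max(1L, 1L - dx):min(nc, nc - dx)
    dst_r <- src_r + dy
    dst_c <- src_c + dx
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + frame[src_r, src_c]
    cnt[dst_r, dst_c] <- cnt[dst_r, dst_c] + 1
  }
  acc / cnt
}

#' Linear min-max contrast stretch
#'
#' Rescales intensities linearly so the data minimum maps to 0 and the
#' maximum to `max_out`. Monotone and rank-preserving; a constant frame is
#' returned unchanged with a warning. Used only on the segmentation copy of
#' images — pixels that are quantified are never stretched.
#'
#' @param frame image frame.
#' @param max_out top of the output range (default 255).
#' @return stretched frame.
#' @export
contrast_stretch <- function(frame, max_out = 255) {
  frame <- image_frame(frame)
  lo <- min(frame); hi <- max(frame)
  if (hi == lo) {
    warning("constant frame: contrast stretch is undefined, returning unchanged")
    return(frame)
  }
  (frame - lo) / (hi - lo) * max_out
}

#' Connected-component labelling
#'
#' Labels the 8-connected components of a binary mask by breadth-first
#' search, in raster order of first encounter (so component 1 contains the
#' first foreground pixel in column-major order).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the particle-analysis convention).
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (is.numeric(mask)) mask <- mask != 0
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  queue <- integer(sum(mask))
  current <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (j in seq_along(dr)) {
        qr <- pr + dr[j]; qc <- pc + dc[j]
        if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
        q <- (qc - 1L) * nr + qr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- current
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

#' Select a connected component of a mask as an ROI
#'
#' @param mask logical matrix (thresholding output).
#' @param mode `"largest_component"` to take the biggest component, or
#'   `"nearest_to_seed"` to take the component whose centroid lies nearest
#'   `seed_point`.
#' @param seed_point `c(x, y)` pixel coordinates (required for seed mode).
#' @return a mask [roi_rect()]/[roi_mask()] covering the chosen component.
#' @export
mask_to_roi <- function(mask, mode = c("largest_component", "nearest_to_seed"),
                        seed_point = NULL) {
  mode <- match.arg(mode)
  if (is.numeric(mask)) mask <- mask != 0
  if (!any(mask)) stopf("no foreground: mask is empty")
  lab <- label_components(mask, 8L)
  n <- max(lab)
  if (mode == "largest_component" || is.null(seed_point)) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    pick <- which.max(sizes)
  } else {
    if (length(seed_point) != 2L) stopf("seed_point must be c(x, y)")
    cent <- component_centroids(lab, n)
    d2 <- (cent[, "x"] - seed_point[1L])^2 + (cent[, "y"] - seed_point[2L])^2
    pick <- which.min(d2)
  }
  roi_mask(lab == pick)
}

component_centroids <- function(lab, n = max(lab)) {
  idx <- which(lab > 0L)
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  l <- lab[idx]
  cbind(x = tapply(cols, l, mean)[as.character(seq_len(n))],
        y = tapply(rows, l, mean)[as.character(seq_len(n))])
}

#' Expand an ROI by k pixels in each direction
#'
#' Morphological dilation by a `(2k+1) x (2k+1)` square structuring element
#' (Chebyshev distance <= k), clipped to the image bounds. Used to build the
#' background ring around a metaphase-plate ROI: the ring is the expansion
#' minus the original ROI.
#'
#' @param roi an ROI.
#' @param k_px expansion radius in pixels (>= 1).
#' @param image_bounds frame dimensions `c(nrow, ncol)`.
#' @return a mask ROI strictly containing the input (after clipping).
#' @export
expand_roi <- function(roi, k_px, image_bounds) {
  if (!is_count(k_px) || k_px < 1L) stopf("k_px must be an integer >= 1")
  m <- roi_to_mask(roi, image_bounds)
  m <- dilate_1d(m, k_px, along = "rows")
  m <- dilate_1d(m, k_px, along = "cols")
  roi_mask(m)
}

# square dilation is separable: dilate along rows then along columns
dilate_1d <- function(m, k, along) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (d in seq_len(k)) {
    if (along == "rows") {
      out[1:(nr - 1), ] <- out[1:(nr - 1), ] | m[(1 + 1):nr, ]
      out[2:nr, ] <- out[2:nr, ] | m[1:(nr - 1), ]
    } else {
      out[, 1:(nc - 1)] <- out[, 1:(nc - 1)] | m[, 2:nc]
      out[, 2:nc] <- out[, 2:nc] | m[, 1:(nc - 1)]
    }
    m <- out
  }
  out
}
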