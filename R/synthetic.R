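#' Synthetic fluorescence microscopy generators
#'
#' Seedable generators that emulate the statistical structure of the
#' recordings the quantification stages were written for, with every ground
#' truth recorded alongside the generated pixels, so the whole pipeline can
#' be exercised and calibrated with no microscopy data. The camera model is
#' Poisson shot noise on the expected photon count plus additive Gaussian
#' read noise, rounded and clamped to the 16-bit range; the optical PSF is
#' folded into the Gaussian widths of the rendered structures. Default frame
#' geometry is 256x256 (the acquisition-scale 512x512 is available via
#' `frame_size`). Every generator is a pure function of its parameters and
#' seed: the same seed gives bit-identical output and the caller's RNG
#' stream is left untouched.
#'
#' @name synthetic
NULL

apply_camera_noise <- function(expected, noise = c("poisson", "none"),
                               read_sd = 5) {
  noise <- match.arg(noise)
  x <- if (noise == "poisson") {
    matrix(stats::rpois(length(expected), lambda = expected),
           nrow(expected), ncol(expected))
  } else expected
  if (read_sd > 0 && noise != "none")
    x <- x + matrix(stats::rnorm(length(x), 0, read_sd), nrow(x), ncol(x))
  x <- round(pmax(x, 0))
  pmin(x, 65535)
}

#' Simulate a condensing paternal pronucleus
#'
#' Renders a time series of a pronucleus whose chromatin compacts from a
#' diffuse Gaussian cloud into a handful of bright foci. A per-frame
#' compaction index ramps linearly from 0 starting 24 frames (240 s at the
#' default 10 s cadence) before NEB at `compaction_rate` per frame, capped
#' at 1; the diffuse component fades and the focal component brightens in
#' proportion. The nucleus centre performs a small random walk to emulate
#' specimen drift.
#'
#' @param n_frames,neb_frame series length and 1-based NEB frame.
#' @param compaction_rate compaction-index increase per frame (0 = static
#'   diffuse chromatin; default 0.04, full compaction ~250 s after onset).
#' @param frame_size square frame side in pixels (default 256).
#' @param noise `"poisson"` or `"none"`.
#' @param read_sd Gaussian read-noise sd in counts (default 5).
#' @param background,diffuse_amp,focus_amp expected counts of the cytoplasmic
#'   background, the diffuse chromatin peak and a fully condensed focus.
#' @param n_foci,nucleus_sigma_px,focus_sigma_px geometry of the rendered
#'   chromatin (foci count, diffuse cloud sigma, focus sigma in pixels).
#' @param drift_sd_px per-frame centre drift sd in pixels.
#' @param centre `c(x, y)` initial nucleus centre (default frame centre).
#' @param seed integer RNG seed (required).
#' @return list with `series` (an [image_series()]), `truth` (data.frame:
#'   `frame`, `centre_x`, `centre_y`, `compaction`) and `params`.
#' @export
simulate_condensing_nucleus <- function(n_frames = 60L, neb_frame = 36L,
                                        compaction_rate = 0.04,
                                        frame_size = 256L,
                                        noise = "poisson", read_sd = 5,
                                        background = 100, diffuse_amp = 600,
                                        focus_amp = 2000, n_foci = 6L,
                                        nucleus_sigma_px = 8,
                                        focus_sigma_px = 1.6,
                                        drift_sd_px = 0.3,
                                        centre = NULL, seed) {
  stopifnot(n_frames >= 1, neb_frame >= 1, compaction_rate >= 0)
  if (missing(seed)) stopf("a seed is required: generators are deterministic")
  if (is.null(centre)) centre <- c(frame_size / 2, frame_size / 2)
  onset <- neb_frame - 24L
  with_seed(seed, {
    foci_dx <- stats::runif(n_foci, -4.5, 4.5)
    foci_dy <- stats::runif(n_foci, -4.5, 4.5)
    foci_amp <- focus_amp * stats::runif(n_foci, 0.7, 1.3)
    drift <- cbind(cumsum(stats::rnorm(n_frames, 0, drift_sd_px)),
                   cumsum(stats::rnorm(n_frames, 0, drift_sd_px)))
    frames <- vector("list", n_frames)
    truth <- data.frame(frame = seq_len(n_frames), centre_x = NA_real_,
                        centre_y = NA_real_, compaction = NA_real_)
    for (t in seq_len(n_frames)) {
      cc <- min(1, max(0, compaction_rate * (t - onset)))
      cx <- centre[1L] + drift[t, 1L]
      cy <- centre[2L] + drift[t, 2L]
      expected <- matrix(background, frame_size, frame_size)
      # render only a window around the nucleus; beyond it the field is background
      w <- 40L
      xr <- max(1L, round(cx) - w):min(frame_size, round(cx) + w)
      yr <- max(1L, round(cy) - w):min(frame_size, round(cy) + w)
      dx2 <- outer(rep(1, length(yr)), (xr - cx)^2)
      dy2 <- outer((yr - cy)^2, rep(1, length(xr)))
      field <- (1 - cc) * diffuse_amp * exp(-(dx2 + dy2) / (2 * nucleus_sigma_px^2))
      for (j in seq_len(n_foci)) {
        fdx2 <- outer(rep(1, length(yr)), (xr - (cx + foci_dx[j]))^2)
        fdy2 <- outer((yr - (cy + foci_dy[j]))^2, rep(1, length(xr)))
        field <- field + cc * foci_amp[j] * exp(-(fdx2 + fdy2) / (2 * focus_sigma_px^2))
      }
      expected[yr, xr] <- expected[yr, xr] + field
      frames[[t]] <- apply_camera_noise(expected, noise, read_sd)
      truth$centre_x[t] <- cx
      truth$centre_y[t] <- cy
      truth$compaction[t] <- cc
    }
    list(series = image_series(frames, dt_s = 10, channel = "chromatin"),
         truth = truth,
         params = list(n_frames = n_frames, neb_frame = neb_frame,
                       onset_frame = onset, compaction_rate = compaction_rate,
                       seed = seed))
  })
}

#' Simulate a two-channel metaphase-plate recording
#'
#' Builds a minimal two-frame, two-channel series around a rectangular
#' metaphase plate: the segmentation channel carries a bright plate for
#' masking; the measurement channel carries expected intensity `F` on the
#' plate and `B` elsewhere. The recorded truth includes the plate area `A`
#' and the quantity the ring-corrected measurement should recover,
#' `A * (F - B)`. With `noise = "none"` the recovery is exact.
#'
#' @param F,B expected measurement-channel counts on and off the plate
#'   (`F > B >= 0`).
#' @param plate_width_px,plate_height_px plate rectangle extent (defaults
#'   8 x 50, area 400 px).
#' @param frame_size square frame side (default 256).
#' @param seg_foreground,seg_background segmentation-channel counts.
#' @param noise,read_sd camera model, as in
#'   [simulate_condensing_nucleus()].
#' @param seed integer RNG seed (required).
#' @return list with `seg_series`, `measure_series`, `annotation` (anaphase
#'   onset at frame 2, so the metaphase frame is frame 1), `truth`
#'   (`A`, `F`, `B`, `expected_corrected`, `plate_mask`) and `params`.
#' @export
simulate_metaphase_plate <- function(F = 2000, B = 200,
                                     plate_width_px = 8L, plate_height_px = 50L,
                                     frame_size = 256L,
                                     seg_foreground = 3000, seg_background = 150,
                                     noise = "poisson", read_sd = 5, seed) {
  if (missing(seed)) stopf("a seed is required: generators are deterministic")
  if (!(F > B) || B < 0) stopf("need plate foreground F > background B >= 0")
  cx <- frame_size %/% 2L; cy <- frame_size %/% 2L
  x0 <- cx - plate_width_px %/% 2L
  y0 <- cy - plate_height_px %/% 2L
  plate <- matrix(FALSE, frame_size, frame_size)
  plate[y0:(y0 + plate_height_px - 1L), x0:(x0 + plate_width_px - 1L)] <- TRUE
  A <- sum(plate)
  seg_expected <- matrix(seg_background, frame_size, frame_size)
  seg_expected[plate] <- seg_foreground
  meas_expected <- matrix(B, frame_size, frame_size)
  meas_expected[plate] <- F
  with_seed(seed, {
    seg_frames <- lapply(1:2, function(i) apply_camera_noise(seg_expected, noise, read_sd))
    meas_frames <- lapply(1:2, function(i) apply_camera_noise(meas_expected, noise, read_sd))
    list(seg_series = image_series(seg_frames, dt_s = 10, channel = "chromatin"),
         measure_series = image_series(meas_frames, dt_s = 10, channel = "measurement"),
         annotation = metaphase_annotation("synthetic", 2L),
         truth = list(A = A, F = F, B = B,
                      expected_corrected = A * (F - B), plate_mask = plate),
         params = list(frame_size = frame_size, noise = noise,
                       read_sd = read_sd, seed = seed))
  })
}

#' Simulate groups of metaphase-plate embryos
#'
#' Generates `n_per_group` plate recordings per condition, scaling the plate
#' foreground excess (`F - B`) by each condition's `scale` and adding
#' lognormal embryo-to-embryo variability (biological scatter plus
#' expression-level differences). Used for end-to-end parameter-recovery
#' checks: the normalized group means should recover the scales.
#'
#' @param scales named numeric vector of true foreground ratios relative to
#'   control (first element is the control, scale 1 by convention).
#' @param n_per_group embryos per condition (default 20).
#' @param bio_cv lognormal coefficient of variation of the per-embryo
#'   foreground excess (default 0.12).
#' @param seed integer RNG seed (required).
#' @inheritParams simulate_metaphase_plate
#' @return list with `embryos` (list of [simulate_metaphase_plate()] results),
#'   `condition` (factor per embryo) and `truth` (per-embryo expected
#'   corrected totals).
#' @export
simulate_plate_groups <- function(scales = c(control = 1, mutant = 0.6),
                                  n_per_group = 20L, bio_cv = 0.12,
                                  F = 2000, B = 200, noise = "poisson",
                                  read_sd = 5, frame_size = 256L, seed) {
  if (missing(seed)) stopf("a seed is required: generators are deterministic")
  if (is.null(names(scales))) names(scales) <- paste0("group", seq_along(scales))
  with_seed(seed, {
    embryo_seeds <- sample.int(.Machine$integer.max %/% 2L,
                               length(scales) * n_per_group)
    sdlog <- sqrt(log(1 + bio_cv^2))
    mult <- stats::rlnorm(length(embryo_seeds), -sdlog^2 / 2, sdlog)
    i <- 0L
    embryos <- list(); condition <- character(0); expected <- numeric(0)
    for (g in names(scales)) {
      for (e in seq_len(n_per_group)) {
        i <- i + 1L
        excess <- (F - B) * scales[[g]] * mult[i]
        embryos[[i]] <- simulate_metaphase_plate(F = B + excess, B = B,
                                                 frame_size = frame_size,
                                                 noise = noise, read_sd = read_sd,
                                                 seed = embryo_seeds[i])
        condition[i] <- g
        expected[i] <- embryos[[i]]$truth$expected_corrected
      }
    }
    list(embryos = embryos, condition = factor(condition, levels = names(scales)),
         truth = list(scales = scales, expected_corrected = expected),
         params = list(n_per_group = n_per_group, bio_cv = bio_cv, seed = seed))
  })
}

#' Simulate a FRAP recording of a half-bleached metaphase plate
#'
#' Renders a horizontal plate; at the bleach frame every pixel on the
#' bleached side of the border has its plate intensity multiplied by
#' `1 - bleach_depth`, and the bleached side then recovers exponentially at
#' `recovery_rate` (per second). The recorded truth includes the border
#' column and the 150x10 profile ROI centred on it, within which the border
#' falls between profile positions 75 and 76.
#'
#' @param pre_frames frames recorded before the bleach (default 2).
#' @param post_frames frames recorded after the bleach (default 10).
#' @param bleach_depth fraction of plate signal removed by the bleach, in
#'   `[0, 1]`.
#' @param recovery_rate exponential recovery rate, per second (0 = no
#'   recovery, the immobile case).
#' @param dt_s frame interval (default 1.5 s, the post-bleach cadence).
#' @param F,B plate and background expected counts.
#' @param frame_size square frame side (default 256).
#' @param noise,read_sd camera model.
#' @param seed integer RNG seed (required).
#' @return list with `series`, `roi` (the 150x10 profile rectangle),
#'   `truth` (`border_col`, `border_profile_pos` = 75.5, `bleach_frame`,
#'   per-frame bleached-side factor) and `params`.
#' @export
simulate_frap_series <- function(pre_frames = 2L, post_frames = 10L,
                                 bleach_depth = 0.6, recovery_rate = 0,
                                 dt_s = 1.5, F = 1500, B = 150,
                                 frame_size = 256L, noise = "poisson",
                                 read_sd = 5, seed) {
  if (missing(seed)) stopf("a seed is required: generators are deterministic")
  if (bleach_depth < 0 || bleach_depth > 1)
    stopf("bleach_depth must lie in [0, 1]")
  cy <- frame_size %/% 2L
  border_col <- frame_size %/% 2L            # bleached side: columns > border_col
  plate_rows <- (cy - 5L):(cy + 6L)          # 12-px-high plate
  plate_cols <- (border_col - 84L):(border_col + 85L)  # 170-px-long plate
  n_frames <- pre_frames + post_frames
  with_seed(seed, {
    frames <- vector("list", n_frames)
    factor_t <- numeric(n_frames)
    for (t in seq_len(n_frames)) {
      fac <- if (t <= pre_frames) 1 else {
        t_since <- (t - pre_frames - 1L) * dt_s
        1 - bleach_depth * exp(-recovery_rate * t_since)
      }
      expected <- matrix(B, frame_size, frame_size)
      expected[plate_rows, plate_cols] <- F
      bleach_cols <- plate_cols[plate_cols > border_col]
      expected[plate_rows, bleach_cols] <- B + (F - B) * fac
      frames[[t]] <- apply_camera_noise(expected, noise, read_sd)
      factor_t[t] <- fac
    }
    roi <- roi_rect(border_col - 74L, cy - 4L, 150L, 10L)
    list(series = image_series(frames, dt_s = dt_s, channel = "frap"),
         roi = roi,
         truth = list(border_col = border_col, border_profile_pos = 75.5,
                      bleach_frame = pre_frames + 1L,
                      bleached_factor = factor_t),
         params = list(pre_frames = pre_frames, post_frames = post_frames,
                       bleach_depth = bleach_depth,
                       recovery_rate = recovery_rate, seed = seed))
  })
}

#' Simulate normalized measurement groups
#'
#' Draws per-group measurement tables for calibrating the statistical
#' decision tree: normal groups with the stated means and standard
#' deviations, or lognormal groups (meanlog = `log(means)`, sdlog = `sds`)
#' for exercising the non-parametric branch.
#'
#' @param means,sds,ns per-group parameters (equal lengths).
#' @param distribution `"normal"` or `"lognormal"`.
#' @param names group names (defaults `group1`, `group2`, ...).
#' @param seed integer RNG seed (required).
#' @return named list of numeric vectors, with a `table` attribute holding
#'   the long-format data.frame (`condition`, `value`).
#' @export
simulate_measurement_groups <- function(means, sds, ns,
                                        distribution = c("normal", "lognormal"),
                                        names = NULL, seed) {
  distribution <- match.arg(distribution)
  if (missing(seed)) stopf("a seed is required: generators are deterministic")
  k <- length(means)
  if (length(sds) != k || length(ns) != k)
    stopf("means, sds and ns must have equal lengths")
  if (is.null(names)) names <- paste0("group", seq_len(k))
  with_seed(seed, {
    groups <- lapply(seq_len(k), function(i) {
      if (distribution == "normal") stats::rnorm(ns[i], means[i], sds[i])
      else stats::rlnorm(ns[i], log(means[i]), sds[i])
    })
    base::names(groups) <- names
    tab <- data.frame(condition = rep(names, ns),
                      value = unlist(groups, use.names = FALSE))
    attr(groups, "table") <- tab
    groups
  })
}
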