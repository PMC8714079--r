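#' Total nuclear intensity time course
#'
#' Per frame, sums the intensity over the maternal and paternal pronucleus
#' ROIs on the max-projected image, subtracts the cytoplasmic background
#' (mean pixel value of a 25x25 cytoplasm region, multiplied by the total
#' nuclear area), and divides by the total nuclear area to report a
#' background-corrected mean pixel value. Max projections are used because
#' the acquired stacks need not encompass the full nuclear volume, so sum
#' projections would depend on stack placement.
#'
#' @param series max-projected (or z-stack) [image_series()].
#' @param maternal_rois,paternal_rois a single ROI (reused every frame) or a
#'   list of per-frame ROIs.
#' @param cytoplasm_roi background region, conventionally a 25x25
#'   [roi_rect()] inside the cytoplasm; a single ROI or per-frame list.
#' @param embryo_id identifier.
#' @return object of class `"nuclear_timecourse"`; its data.frame form has
#'   columns `time_s`, `mean_value`, `area_px`.
#' @export
nuclear_timecourse <- function(series, maternal_rois, paternal_rois,
                               cytoplasm_roi, embryo_id = NA) {
  nt <- n_frames(series)
  mat <- per_frame_rois(maternal_rois, nt)
  pat <- per_frame_rois(paternal_rois, nt)
  cyt <- per_frame_rois(cytoplasm_roi, nt)
  mean_value <- numeric(nt)
  area_px <- numeric(nt)
  for (t in seq_len(nt)) {
    frame <- project_timepoint(series, t, max_project)
    dm <- dim(frame)
    mm <- roi_to_mask(mat[[t]], dm)
    pm <- roi_to_mask(pat[[t]], dm)
    if (any(mm & pm))
      stopf("maternal and paternal ROIs overlap at frame %d", t)
    a <- sum(mm) + sum(pm)
    total <- sum(frame[mm]) + sum(frame[pm])
    bg <- mean(roi_pixels(frame, cyt[[t]]))
    mean_value[t] <- (total - a * bg) / a
    area_px[t] <- a
  }
  structure(list(embryo_id = embryo_id,
                 times_s = (seq_len(nt) - 1L) * series$dt_s,
                 mean_value = mean_value, area_px = area_px),
            class = "nuclear_timecourse")
}

per_frame_rois <- function(rois, nt) {
  if (inherits(rois, "roi")) return(rep(list(rois), nt))
  if (!is.list(rois) || length(rois) != nt)
    stopf("per-frame ROIs must be a single roi or a list of length %d", nt)
  rois
}

#' @export
as.data.frame.nuclear_timecourse <- function(x, ...) {
  data.frame(embryo_id = x$embryo_id, time_s = x$times_s,
             mean_value = x$mean_value, area_px = x$area_px)
}

#' Spindle pole-to-pole distance
#'
#' Euclidean distance between two manually annotated pole positions,
#' converted to micrometres. Fractional (sub-pixel) coordinates are used
#' as given.
#'
#' @param p1,p2 `c(x, y)` pole coordinates in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @return distance in micrometres.
#' @export
pole_distance <- function(p1, p2, pixel_size_um) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be > 0")
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) * pixel_size_um
}

#' Frame times aligned to a reference event
#'
#' Converts 1-based frame indices to seconds relative to a reference frame
#' (anaphase onset for pole-distance curves, NEB for condensation curves).
#'
#' @param frames integer frame indices.
#' @param zero_frame frame assigned time 0.
#' @param dt_s frame interval, seconds.
#' @return numeric vector of times in seconds (negative before the event).
#' @export
align_times <- function(frames, zero_frame, dt_s = 10) {
  (as.numeric(frames) - zero_frame) * dt_s
}

#' NEB-to-anaphase interval
#'
#' @param neb_frame,anaphase_frame 1-based frame indices with
#'   `anaphase_frame > neb_frame`.
#' @param dt_s frame interval, seconds (default 10).
#' @return interval in seconds.
#' @export
neb_to_anaphase_interval <- function(neb_frame, anaphase_frame, dt_s = 10) {
  if (!is_count(neb_frame) || !is_count(anaphase_frame))
    stopf("frame indices must be integers")
  if (anaphase_frame <= neb_frame)
    stopf("anaphase onset (frame %d) must come after NEB (frame %d)",
          anaphase_frame, neb_frame)
  (anaphase_frame - neb_frame) * dt_s
}

#' FRAP line profiles across a half-bleached metaphase plate
#'
#' For each requested timepoint, extracts the 150x10 (by default any
#' `L x w`) rectangle and averages over the `w` transverse pixels at each of
#' the `L` positions along the long axis, giving one mean-intensity profile
#' per timepoint. `orientation` declares which rectangle side is the long
#' (profile) axis.
#'
#' @param series an [image_series()] (single-plane FRAP recordings).
#' @param roi a [roi_rect()] covering the plate, centred on the bleach
#'   border.
#' @param orientation `"horizontal"` (profile along x) or `"vertical"`
#'   (profile along y).
#' @param timepoints frame indices to profile (default all).
#' @param labels optional names for the timepoints (e.g. "pre-bleach").
#' @return list of `"frap_profile"` objects (`positions`, `intensity`,
#'   `label`, `frame`).
#' @export
frap_profiles <- function(series, roi, orientation = c("horizontal", "vertical"),
                          timepoints = seq_len(n_frames(series)),
                          labels = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(roi, "roi"), roi$kind == "rect")
  if (!is.null(labels) && length(labels) != length(timepoints))
    stopf("labels must match timepoints in length")
  lapply(seq_along(timepoints), function(i) {
    t <- timepoints[i]
    frame <- project_timepoint(series, t, max_project)
    block <- crop_frame(frame, roi)
    prof <- if (orientation == "horizontal") colMeans(block) else rowMeans(block)
    structure(list(positions = seq_along(prof), intensity = as.numeric(prof),
                   label = if (is.null(labels)) paste0("frame_", t) else labels[i],
                   frame = t),
              class = "frap_profile")
  })
}

#' Average FRAP profiles over biological replicates
#'
#' Positionwise mean and sample standard deviation over replicate profiles
#' of one timepoint.
#'
#' @param replicates list of `"frap_profile"` objects of equal length.
#' @return a `"frap_profile"` with `intensity` (mean) and `sd` per position.
#' @export
average_profiles <- function(replicates) {
  if (length(replicates) < 1L) stopf("need at least one profile")
  stopifnot(all(vapply(replicates, inherits, logical(1), "frap_profile")))
  lens <- vapply(replicates, function(p) length(p$intensity), integer(1))
  if (length(unique(lens)) != 1L)
    stopf("replicate profiles differ in length (%s)", paste(unique(lens), collapse = ", "))
  m <- do.call(cbind, lapply(replicates, function(p) p$intensity))
  structure(list(positions = seq_len(nrow(m)),
                 intensity = rowMeans(m),
                 sd = if (ncol(m) > 1L) apply(m, 1L, stats::sd) else rep(0, nrow(m)),
                 label = replicates[[1L]]$label,
                 n = ncol(m)),
            class = "frap_profile")
}

#' Embryonic lethality from egg and hatchling counts
#'
#' Lethality is the fraction of laid eggs that fail to hatch,
#' `(laid - hatched) / laid`, computed per replicate; the per-condition
#' summary is the mean over biological replicates.
#'
#' @param records data.frame with columns `condition`, `replicate`, `laid`,
#'   `hatched`.
#' @return list with `per_replicate` (records plus `lethality`) and
#'   `per_condition` (condition, mean lethality, n replicates).
#' @export
embryonic_lethality <- function(records) {
  req <- c("condition", "replicate", "laid", "hatched")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stopf("records must have columns %s", paste(req, collapse = ", "))
  if (any(records$laid <= 0))
    stopf("laid egg counts must be positive")
  if (any(records$hatched < 0) || any(records$hatched > records$laid))
    stopf("hatchling counts must satisfy 0 <= hatched <= laid")
  per <- records
  per$lethality <- (per$laid - per$hatched) / per$laid
  agg <- aggregate(lethality ~ condition, data = per, FUN = mean)
  agg$n_replicates <- aggregate(lethality ~ condition, data = per, FUN = length)$lethality
  list(per_replicate = per, per_condition = agg)
}
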