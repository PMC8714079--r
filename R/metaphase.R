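#' Metaphase annotation
#'
#' Records the manually scored anaphase-onset frame for one embryo (the
#' first frame at which sister chromatids appear to separate). Frames are
#' 1-based, so a valid onset is >= 2: the metaphase frame is the last frame
#' before onset.
#'
#' @param embryo_id identifier.
#' @param anaphase_onset_frame 1-based frame index of anaphase onset.
#' @param seg_channel,measure_channel optional channel-role labels.
#' @return object of class `"metaphase_annotation"`.
#' @export
metaphase_annotation <- function(embryo_id, anaphase_onset_frame,
                                 seg_channel = "chromatin",
                                 measure_channel = "measurement") {
  if (!is_count(anaphase_onset_frame))
    stopf("anaphase_onset_frame must be an integer frame index")
  structure(list(embryo_id = embryo_id,
                 anaphase_onset_frame = as.integer(anaphase_onset_frame),
                 seg_channel = seg_channel, measure_channel = measure_channel),
            class = "metaphase_annotation")
}

#' Select the metaphase frame
#'
#' The metaphase frame is defined as the last frame before anaphase onset.
#'
#' @param annotation a [metaphase_annotation()] or a bare onset frame index.
#' @return 1-based frame index of the metaphase frame.
#' @export
select_metaphase_frame <- function(annotation) {
  onset <- if (inherits(annotation, "metaphase_annotation"))
    annotation$anaphase_onset_frame else annotation
  if (!is_count(onset)) stopf("anaphase onset must be an integer frame index")
  if (onset < 2L) stopf("no pre-anaphase frame: anaphase onset at frame %d", onset)
  as.integer(onset) - 1L
}

#' Ring-background-corrected ROI intensity
#'
#' Estimates the local per-pixel background from the ring between an ROI and
#' its expansion, then subtracts `area * mean background` from the ROI total:
#' `mean_background = (total_expanded - total_roi) / (expanded_area - roi_area)`
#' and `corrected_total = total_roi - roi_area * mean_background`. A negative
#' corrected total is reported as-is (with a flag), never clipped — clipping
#' would bias group means.
#'
#' @param measure_frame frame to quantify (typically a sum projection).
#' @param roi the plate ROI.
#' @param expanded the expanded ROI (must strictly contain `roi`).
#' @param embryo_id,frame_index optional provenance carried into the result.
#' @return object of class `"intensity_measurement"`.
#' @export
background_corrected_intensity <- function(measure_frame, roi, expanded,
                                           embryo_id = NA, frame_index = NA) {
  measure_frame <- image_frame(measure_frame)
  dm <- dim(measure_frame)
  if (!roi_contains(expanded, roi, dm))
    stopf("expanded ROI must contain the measurement ROI")
  a_roi <- roi_area(roi)
  a_exp <- roi_area(expanded)
  if (a_exp <= a_roi) stopf("empty background ring: expanded ROI adds no area")
  total_roi <- total_intensity(measure_frame, roi)
  total_expanded <- total_intensity(measure_frame, expanded)
  mean_bg <- (total_expanded - total_roi) / (a_exp - a_roi)
  total_bg <- a_roi * mean_bg
  corrected <- total_roi - total_bg
  structure(list(embryo_id = embryo_id, frame_index = frame_index,
                 roi = roi, expanded_roi = expanded,
                 total_roi = total_roi, total_expanded = total_expanded,
                 mean_background = mean_bg, total_background = total_bg,
                 corrected_total = corrected,
                 negative_flag = corrected < 0,
                 normalized = NA_real_),
            class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, ...) {
  cat(sprintf(
    "<intensity_measurement> embryo %s, frame %s\n  ROI %d px (+ring %d px): total %.6g, mean bg %.6g/px, corrected %.6g%s\n",
    format(x$embryo_id), format(x$frame_index),
    roi_area(x$roi), roi_area(x$expanded_roi) - roi_area(x$roi),
    x$total_roi, x$mean_background, x$corrected_total,
    if (isTRUE(x$negative_flag)) " [negative]" else ""))
  invisible(x)
}

#' Metaphase-plate intensity pipeline
#'
#' Reproduces the full plate measurement for one embryo: at the metaphase
#' frame, the segmentation channel is max-projected and auto-thresholded by
#' maximum entropy; the resulting mask gives the plate ROI (largest
#' component, or the component nearest `seed_point`); the ROI is expanded by
#' `expand_px` pixels in each direction to define the background ring; the
#' measurement channel is sum-projected and quantified with
#' [background_corrected_intensity()]. With `measure_series = NULL` the
#' single channel feeds both paths (max projection for the ROI, sum
#' projection for the measurement).
#'
#' @param seg_series segmentation-channel [image_series()].
#' @param measure_series measurement-channel series, or `NULL` for
#'   single-channel mode.
#' @param annotation a [metaphase_annotation()].
#' @param expand_px background-ring expansion in pixels (default 5).
#' @param seed_point optional `c(x, y)` to pick the plate component.
#' @return an `"intensity_measurement"`.
#' @export
metaphase_pipeline <- function(seg_series, measure_series = NULL, annotation,
                               expand_px = 5L, seed_point = NULL) {
  if (is.null(measure_series)) measure_series <- seg_series
  if (n_frames(seg_series) != n_frames(measure_series) ||
      !identical(frame_dim(seg_series$frames[[1L]]),
                 frame_dim(measure_series$frames[[1L]])))
    stopf("segmentation and measurement channels must match in length and shape")
  k <- select_metaphase_frame(annotation)
  if (k > n_frames(seg_series))
    stopf("metaphase frame %d lies beyond the %d-frame series", k,
          n_frames(seg_series))
  seg <- project_timepoint(seg_series, k, max_project)
  th <- max_entropy_threshold(build_histogram(seg))
  mask <- apply_threshold(seg, th)
  if (!any(mask))
    stopf("segmentation produced an empty mask at frame %d (max-entropy level %g)",
          k, th$level)
  mode <- if (is.null(seed_point)) "largest_component" else "nearest_to_seed"
  roi <- mask_to_roi(mask, mode, seed_point)
  expanded <- expand_roi(roi, expand_px, dim(seg))
  meas <- project_timepoint(measure_series, k, sum_project)
  background_corrected_intensity(meas, roi, expanded,
                                 embryo_id = annotation$embryo_id,
                                 frame_index = k)
}

#' Normalize measurements to the control mean
#'
#' Divides every value by the mean of the control measurements, so the
#' control group averages exactly 1 and other groups are expressed as
#' fractions of the control level.
#'
#' @param values numeric vector of measurements.
#' @param control_values numeric vector of control measurements (non-empty,
#'   nonzero mean).
#' @return normalized numeric vector.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L || !all(is.finite(control_values)))
    stopf("control measurements must be non-empty and finite")
  m <- mean(control_values)
  if (m == 0) stopf("control mean is zero: normalization undefined")
  values / m
}
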