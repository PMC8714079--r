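#' Image frames, z-stacks and time series
#'
#' An image frame is a plain numeric matrix of non-negative intensities
#' (rows = y, columns = x, 1-based indices). A z-stack wraps an ordered list
#' of same-shaped frames with the axial step recorded as metadata; an image
#' series wraps one z-stack (or single projected frame) per timepoint together
#' with the frame interval and pixel size. Intensities are treated as
#' unitless camera counts; 8- and 16-bit data are both accepted.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @return `image_frame()` returns the validated matrix.
#' @export
image_frame <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("image frame must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("image frame must have at least one row and one column")
  if (anyNA(pixels) || any(pixels < 0))
    stopf("image frame intensities must be non-negative and finite")
  pixels
}

#' @rdname image_frame
#' @param slices list of image frames of identical shape, ordered bottom to top.
#' @param z_step_um axial step between slices, micrometres.
#' @export
z_stack <- function(slices, z_step_um = 0.8) {
  if (is.matrix(slices)) slices <- list(slices)
  if (!is.list(slices) || length(slices) < 1L) stopf("empty stack")
  slices <- lapply(slices, image_frame)
  d <- dim(slices[[1L]])
  ok <- vapply(slices, function(s) identical(dim(s), d), logical(1))
  if (!all(ok)) stopf("all slices in a z-stack must have the same shape")
  if (!is.numeric(z_step_um) || z_step_um <= 0) stopf("z_step_um must be > 0")
  structure(list(slices = slices, z_step_um = z_step_um), class = "zstack")
}

#' @rdname image_frame
#' @param frames list with one element per timepoint; each element is a
#'   `zstack` or a single projected frame (matrix).
#' @param dt_s frame interval in seconds (default 10, the acquisition cadence
#'   of the recordings this package quantifies).
#' @param pixel_size_um lateral pixel size in micrometres (default 0.254,
#'   a 16 um camera pixel behind a 63x objective).
#' @param channel optional channel label.
#' @export
image_series <- function(frames, dt_s = 10, pixel_size_um = 0.254,
                         channel = NA_character_) {
  if (!is.list(frames) || length(frames) < 1L)
    stopf("an image series needs at least one timepoint")
  frames <- lapply(frames, function(f) {
    if (inherits(f, "zstack")) f else image_frame(f)
  })
  dims <- lapply(frames, frame_dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stopf("all timepoints in a series must have the same frame shape")
  if (!is.numeric(dt_s) || dt_s <= 0) stopf("dt_s must be > 0")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be > 0")
  structure(list(frames = frames, dt_s = dt_s, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "image_series")
}

frame_dim <- function(f) if (inherits(f, "zstack")) dim(f$slices[[1L]]) else dim(f)

n_frames <- function(series) length(series$frames)

#' @export
print.image_series <- function(x, ...) {
  d <- frame_dim(x$frames[[1L]])
  nz <- if (inherits(x$frames[[1L]], "zstack")) length(x$frames[[1L]]$slices) else 1L
  cat(sprintf("<image_series> %d timepoints, %dx%d px, %d z-slice(s), dt = %g s%s\n",
              length(x$frames), d[1L], d[2L], nz, x$dt_s,
              if (is.na(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Intensity projections along z
#'
#' `max_project()` takes the per-pixel maximum across the slices of a z-stack
#' (used on the chromatin channel for segmentation and display);
#' `sum_project()` takes the per-pixel sum, accumulating in double precision
#' so the result may exceed the input bit depth (used on the measurement
#' channel, where total intensity must be conserved).
#'
#' @param stack a `zstack`, a list of same-shaped frames, or a single frame
#'   (returned unchanged).
#' @return an image frame (numeric matrix).
#' @export
max_project <- function(stack) {
  slices <- project_slices(stack)
  out <- Reduce(pmax, slices)
  storage.mode(out) <- "double"
  out
}

#' @rdname max_project
#' @export
sum_project <- function(stack) {
  slices <- project_slices(stack)
  Reduce(`+`, lapply(slices, function(s) s * 1.0))
}

project_slices <- function(stack) {
  if (inherits(stack, "zstack")) return(stack$slices)
  if (is.matrix(stack)) return(list(image_frame(stack)))
  if (is.list(stack)) {
    if (length(stack) == 0L) stopf("empty stack")
    return(z_stack(stack)$slices)
  }
  stopf("empty stack")
}

#' Timepoint projection helper
#'
#' Projects one timepoint of a series: z-stacks are projected with the given
#' projector, already-projected frames pass through.
#' @keywords internal
project_timepoint <- function(series, i, projector = max_project) {
  f <- series$frames[[i]]
  if (inherits(f, "zstack")) projector(f) else f
}

#' Total intensity inside a region of interest
#'
#' Sums the pixel values of `frame` inside `roi`. Additive over disjoint
#' ROIs; the whole-image ROI returns the grand sum.
#'
#' @param frame image frame (numeric matrix).
#' @param roi an [roi_rect()] or [roi_mask()].
#' @return numeric scalar.
#' @export
total_intensity <- function(frame, roi) {
  frame <- image_frame(frame)
  sum(roi_pixels(frame, roi))
}

#' Crop a frame to a rectangular ROI
#'
#' @param frame image frame.
#' @param roi a rectangle ROI (mask ROIs cannot be cropped to a matrix).
#' @return matrix of size `height x width`.
#' @export
crop_frame <- function(frame, roi) {
  frame <- image_frame(frame)
  if (!inherits(roi, "roi") || roi$kind != "rect")
    stopf("crop_frame needs a rectangle ROI")
  check_rect_bounds(roi, dim(frame))
  frame[roi$y0:(roi$y0 + roi$height - 1L), roi$x0:(roi$x0 + roi$width - 1L),
        drop = FALSE]
}
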