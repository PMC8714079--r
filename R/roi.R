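#' Regions of interest
#'
#' Two ROI kinds cover all measurements in the package: axis-aligned
#' rectangles (the 21x21 condensation ROI, the 25x25 cytoplasm background
#' ROI, the 150x10 FRAP profile ROI) and free-form binary masks (segmented
#' metaphase plates and pronuclei). Rectangles use 1-based inclusive pixel
#' coordinates: `x0`, `y0` is the top-left pixel (x = column, y = row) and
#' the ROI covers `width` columns and `height` rows.
#'
#' @param x0,y0 1-based column/row of the top-left pixel.
#' @param width,height extent in pixels (>= 1).
#' @return an object of class `"roi"`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  if (!is_count(x0) || !is_count(y0) || x0 < 1 || y0 < 1)
    stopf("x0 and y0 must be positive integers (1-based)")
  if (!is_count(width) || !is_count(height) || width < 1 || height < 1)
    stopf("ROI width and height must be >= 1")
  structure(list(kind = "rect", x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' @rdname roi_rect
#' @param mask logical (or 0/1) matrix the same shape as the source frame;
#'   `TRUE` marks ROI membership. Must contain at least one pixel.
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stopf("mask must be logical or 0/1")
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) stopf("empty-mask ROI: area must be >= 1")
  structure(list(kind = "mask", mask = mask), class = "roi")
}

#' @rdname roi_rect
#' @param roi an ROI.
#' @export
roi_area <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  if (roi$kind == "rect") roi$width * roi$height else sum(roi$mask)
}

#' @export
print.roi <- function(x, ...) {
  if (x$kind == "rect")
    cat(sprintf("<roi> rect %dx%d at (x=%d, y=%d), area %d px\n",
                x$width, x$height, x$x0, x$y0, roi_area(x)))
  else
    cat(sprintf("<roi> mask %dx%d, area %d px\n",
                nrow(x$mask), ncol(x$mask), roi_area(x)))
  invisible(x)
}

check_rect_bounds <- function(roi, dm) {
  if (roi$x0 + roi$width - 1L > dm[2L] || roi$y0 + roi$height - 1L > dm[1L])
    stopf("ROI [x %d..%d, y %d..%d] exceeds the %dx%d frame bounds",
          roi$x0, roi$x0 + roi$width - 1L, roi$y0, roi$y0 + roi$height - 1L,
          dm[1L], dm[2L])
  invisible(TRUE)
}

#' Convert an ROI to a full-frame logical mask
#'
#' @param roi an ROI.
#' @param dim frame dimensions `c(nrow, ncol)`.
#' @return logical matrix.
#' @export
roi_to_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "roi"))
  if (roi$kind == "mask") {
    if (!identical(base::dim(roi$mask), as.integer(dim)))
      stopf("mask ROI shape does not match frame shape")
    return(roi$mask)
  }
  check_rect_bounds(roi, dim)
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[roi$y0:(roi$y0 + roi$height - 1L), roi$x0:(roi$x0 + roi$width - 1L)] <- TRUE
  m
}

#' Extract the pixel values covered by an ROI
#'
#' @inheritParams roi_to_mask
#' @param frame image frame.
#' @return numeric vector (column-major order for rectangles).
#' @export
roi_pixels <- function(frame, roi) {
  stopifnot(inherits(roi, "roi"))
  if (roi$kind == "rect") {
    check_rect_bounds(roi, dim(frame))
    return(as.vector(frame[roi$y0:(roi$y0 + roi$height - 1L),
                           roi$x0:(roi$x0 + roi$width - 1L)]))
  }
  if (!identical(dim(roi$mask), dim(frame)))
    stopf("mask ROI shape does not match frame shape")
  frame[roi$mask]
}

#' Set relations between ROIs
#' @keywords internal
roi_contains <- function(outer, inner, dim) {
  mo <- roi_to_mask(outer, dim)
  mi <- roi_to_mask(inner, dim)
  !any(mi & !mo)
}
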