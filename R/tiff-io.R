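#' Read and write multi-page TIFF time series
#'
#' A series is stored as one page per (timepoint, z-slice, channel)
#' combination, with the page order declared by a dimension-order string:
#' the string lists the leading axes from slowest- to fastest-varying and
#' always ends in `"YX"`. Supported orders are `"TYX"`, `"TZYX"`, `"TCYX"`
#' and `"TZCYX"` (so for `"TZCYX"` channel varies fastest, then z, then
#' time — the hyperstack convention). Pixel values are written as unsigned
#' integers at the declared bit depth and the round trip is bit-exact for
#' 8- and 16-bit data.
#'
#' @param series an [image_series()], or a list of them (one per channel) for
#'   multi-channel orders.
#' @param path TIFF file path.
#' @param order dimension-order string, e.g. `"TZYX"`.
#' @param bits bits per sample, 8 or 16.
#' @return `write_series()` returns `path` invisibly. `read_series()` returns
#'   an `image_series`, or a list of them (one per channel) when the order
#'   declares a C axis.
#' @export
write_series <- function(series, path, order = "TZYX", bits = 16L) {
  ax <- parse_dim_order(order)
  channels <- if (inherits(series, "image_series")) list(series) else series
  if (!all(vapply(channels, inherits, logical(1), "image_series")))
    stopf("series must be an image_series or a list of image_series")
  if (ax$has_c && length(channels) < 2L)
    stopf("order %s declares a C axis but a single channel was given", order)
  if (!ax$has_c && length(channels) != 1L)
    stopf("order %s has no C axis but %d channels were given", order,
          length(channels))
  nt <- length(channels[[1L]]$frames)
  nz <- series_nz(channels[[1L]])
  for (ch in channels) {
    if (length(ch$frames) != nt || series_nz(ch) != nz)
      stopf("all channels must share T and Z extents")
  }
  if (!ax$has_z && nz != 1L)
    stopf("order %s has no Z axis but the series has %d slices", order, nz)
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  maxval <- 2^bits - 1
  pages <- vector("list", nt * nz * length(channels))
  i <- 0L
  for (idx in page_index_grid(ax, nt, nz, length(channels))) {
    m <- series_slice(channels[[idx[3L]]], idx[1L], idx[2L])
    if (any(m > maxval) || any(m != round(m)))
      stopf("pixel values must be integers in [0, %d] for %d-bit output",
            maxval, bits)
    i <- i + 1L
    pages[[i]] <- m / maxval
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' @rdname write_series
#' @param n_z number of z-slices per timepoint (for orders with a Z axis).
#' @param n_channels number of channels (for orders with a C axis).
#' @param dt_s,pixel_size_um series metadata to attach (not stored in the
#'   TIFF container).
#' @export
read_series <- function(path, order = "TZYX", n_z = 1L, n_channels = 1L,
                        dt_s = 10, pixel_size_um = 0.254) {
  ax <- parse_dim_order(order)
  if (!ax$has_z && n_z != 1L) stopf("order %s has no Z axis", order)
  if (!ax$has_c && n_channels != 1L) stopf("order %s has no C axis", order)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop any extra sample planes
    storage.mode(p) <- "double"
    p
  })
  per_t <- n_z * n_channels
  if (length(pages) %% per_t != 0L)
    stopf("file holds %d pages, not a multiple of Z*C = %d: truncated or wrong layout",
          length(pages), per_t)
  nt <- length(pages) %/% per_t
  out <- vector("list", n_channels)
  grid <- page_index_grid(ax, nt, n_z, n_channels)
  store <- lapply(seq_len(n_channels), function(c)
    lapply(seq_len(nt), function(t) vector("list", n_z)))
  for (i in seq_along(grid)) {
    idx <- grid[[i]]
    store[[idx[3L]]][[idx[1L]]][[idx[2L]]] <- pages[[i]]
  }
  for (c in seq_len(n_channels)) {
    frames <- lapply(store[[c]], function(slices) {
      if (n_z == 1L) slices[[1L]] else z_stack(slices)
    })
    out[[c]] <- image_series(frames, dt_s = dt_s, pixel_size_um = pixel_size_um,
                             channel = if (n_channels > 1L) as.character(c) else NA_character_)
  }
  if (n_channels == 1L) out[[1L]] else out
}

parse_dim_order <- function(order) {
  if (!is.character(order) || length(order) != 1L)
    stopf("dimension order must be a single string")
  chars <- strsplit(order, "")[[1L]]
  n <- length(chars)
  if (n < 3L || chars[n - 1L] != "Y" || chars[n] != "X")
    stopf("dimension order %s must end in YX", order)
  lead <- chars[seq_len(n - 2L)]
  bad <- setdiff(lead, c("T", "Z", "C"))
  if (length(bad) > 0L)
    stopf("unrecognized axis '%s' in dimension order %s", bad[1L], order)
  if (anyDuplicated(chars) > 0L)
    stopf("duplicated axis '%s' in dimension order %s",
          chars[anyDuplicated(chars)], order)
  if (!"T" %in% lead) stopf("dimension order %s lacks the T axis", order)
  if (!identical(lead[1L], "T"))
    stopf("axis '%s' may not vary slower than T in order %s", lead[1L], order)
  list(lead = lead, has_z = "Z" %in% lead, has_c = "C" %in% lead)
}

# enumerate (t, z, c) page indices in declared order, last axis fastest
page_index_grid <- function(ax, nt, nz, nc) {
  extents <- c(T = nt, Z = nz, C = nc)[ax$lead]
  grid <- list(c(t = 1L, z = 1L, c = 1L))
  out <- vector("list", prod(extents))
  i <- 0L
  rec <- function(depth, idx) {
    if (depth > length(ax$lead)) {
      i <<- i + 1L
      out[[i]] <<- idx
      return(invisible())
    }
    axname <- ax$lead[depth]
    slot <- match(axname, c("T", "Z", "C"))
    for (v in seq_len(extents[[depth]])) {
      idx[slot] <- v
      rec(depth + 1L, idx)
    }
  }
  rec(1L, c(1L, 1L, 1L))
  out
}

series_nz <- function(series) {
  f <- series$frames[[1L]]
  if (inherits(f, "zstack")) length(f$slices) else 1L
}

series_slice <- function(series, t, z) {
  f <- series$frames[[t]]
  if (inherits(f, "zstack")) f$slices[[z]] else f
}
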