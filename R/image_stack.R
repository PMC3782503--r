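#' Calibrated multichannel image stack
#'
#' Container for a fluorescence volume with axes ordered `(z, c, y, x)` and
#' physical calibration. Intensities are stored as doubles on a 16-bit-range
#' convention (`[0, 65535]`), though any finite non-negative values are
#' accepted. Pixel coordinates are 1-based (`row = y`, `col = x`); the
#' physical position of a pixel centre is `(index - 1) * spacing`.
#'
#' @param data numeric array. Accepted shapes: `(y, x)` (a single plane),
#'   `(z, y, x)` (single-channel volume, `channels = 1` required), or
#'   `(z, c, y, x)`.
#' @param pixel_size_xy lateral calibration, micrometres per pixel.
#' @param step_z axial step between optical sections, micrometres. The
#'   default 0.45 matches typical confocal z-series acquisition for
#'   invadopodia imaging.
#' @param channel_names character vector, one label per channel.
#'
#' @return An object of class `ImageStack`: a list with elements `data`
#'   (the `(z, c, y, x)` array), `pixel_size_xy`, `step_z` and
#'   `channel_names`.
#' @examples
#' img <- matrix(runif(64, 0, 1000), 8, 8)
#' s <- ImageStack(img, pixel_size_xy = 0.1)
#' dim(s$data)  # 1 1 8 8
#' @export
ImageStack <- function(data, pixel_size_xy = 1, step_z = 0.45,
                       channel_names = NULL) {
  if (!is.numeric(data)) stop("`data` must be numeric")
  d <- dim(data)
  if (is.null(d)) stop("`data` must be a matrix or array")
  if (length(d) == 2L) {
    data <- array(data, c(1L, 1L, d[1L], d[2L]))
  } else if (length(d) == 3L) {
    data <- array(data, c(d[1L], 1L, d[2L], d[3L]))
  } else if (length(d) != 4L) {
    stop("`data` must have 2, 3 or 4 dimensions (z, c, y, x)")
  }
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_xy) || length(pixel_size_xy) != 1L ||
      pixel_size_xy <= 0) {
    stop("`pixel_size_xy` must be a positive scalar (um/pixel)")
  }
  if (!is.numeric(step_z) || length(step_z) != 1L || step_z <= 0) {
    stop("`step_z` must be a positive scalar (um)")
  }
  nc <- dim(data)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("`channel_names` must have one entry per channel")
  }
  structure(
    list(data = data, pixel_size_xy = pixel_size_xy, step_z = step_z,
         channel_names = as.character(channel_names)),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d plane(s) x %d channel(s), %d x %d px (y x x)\n",
    d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  pixel size %.4g um/px, z step %.4g um\n",
              x$pixel_size_xy, x$step_z))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Extract one channel of a stack
#'
#' @param stack an [ImageStack].
#' @param channel channel index or name.
#' @param drop if `TRUE` (default) return a `(y, x)` matrix when the stack
#'   has a single plane, else a `(z, y, x)` array.
#' @return numeric matrix or array of intensities.
#' @export
get_channel <- function(stack, channel, drop = TRUE) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(stack$data)
  if (channel < 1L || channel > d[2L]) stop("channel index out of range")
  out <- stack$data[, channel, , , drop = FALSE]
  out <- array(out, c(d[1L], d[3L], d[4L]))
  if (drop && d[1L] == 1L) out <- matrix(out, d[3L], d[4L])
  out
}
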