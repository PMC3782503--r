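#' Write an image stack to multi-page TIFF
#'
#' Pages are written z-major (all channels of plane 1, then plane 2, ...).
#' Intensities are scaled by `1/65535` into the `[0, 1]` range the TIFF
#' writer expects and stored at 32 bits per sample; the quantization step is
#' about 1.5e-5 intensity units, far below photon noise at any realistic
#' gain. Calibration and channel labels go to an OME-style JSON sidecar
#' (`<path>.json`) with keys `PhysicalSizeX/Y/Z`, `SizeZ`, `SizeC` and
#' `ChannelNames`.
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path.
#' @param bits bits per sample for storage (32, the default, or 16 to
#'   quantize to 16-bit).
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, bits = 32L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!bits %in% c(16L, 32L)) stop("`bits` must be 16 or 32")
  d <- dim(stack$data)
  if (max(stack$data) > 65535) stop("intensities exceed the 16-bit-range convention")
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (z in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      pages[[k]] <- matrix(stack$data[z, ch, , ], d[3L], d[4L]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "deflate")
  meta <- list(
    SizeZ = d[1L], SizeC = d[2L], SizeY = d[3L], SizeX = d[4L],
    PhysicalSizeX = stack$pixel_size_xy, PhysicalSizeY = stack$pixel_size_xy,
    PhysicalSizeZ = stack$step_z, PhysicalSizeUnit = "um",
    ChannelNames = as.list(stack$channel_names), DimensionOrder = "ZCYX"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF into an ImageStack
#'
#' If an OME-style JSON sidecar written by [write_stack()] is present the
#' `(z, c)` page layout and physical calibration are taken from it.
#' Otherwise every page is treated as one z plane of a single channel and
#' the calibration defaults to 1 um/pixel with a warning.
#'
#' @param path TIFF path.
#' @return An [ImageStack] with axes `(z, c, y, x)`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # collapse RGB pages
  })
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (is.null(meta)) {
    warning("no calibration sidecar for ", path,
            "; assuming 1 channel, pixel size 1.0 um")
    nz <- length(pages); nc <- 1L
    px <- 1; sz <- 0.45; chn <- NULL
  } else {
    nz <- as.integer(meta$SizeZ); nc <- as.integer(meta$SizeC)
    if (nz * nc != length(pages)) stop("TIFF page count does not match sidecar")
    px <- meta$PhysicalSizeX; sz <- meta$PhysicalSizeZ
    chn <- unlist(meta$ChannelNames)
  }
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, c(nz, nc, ny, nx))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      arr[z, ch, , ] <- pages[[k]] * 65535
      k <- k + 1L
    }
  }
  ImageStack(arr, pixel_size_xy = px, step_z = sz, channel_names = chn)
}

#' Write a label image (cell masks) as TIFF
#'
#' Integer labels are stored directly in 16-bit pages (label/65535 scaling),
#' so up to 65535 objects round-trip exactly.
#'
#' @param labels integer matrix, 0 = background.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "deflate")
  invisible(path)
}

#' Read a label image written by [write_labels()]
#' @param path TIFF path.
#' @return integer matrix of labels.
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a patient cohort table from CSV
#'
#' Expected header: `id, marker_fraction, age, grade, lymph_node, dimension,
#' PgR, HER2, Ki67, npi` (extra columns are kept). Factor-like columns are
#' read as character; `status` and `npi_group` are (re)derived from
#' `marker_fraction` and `npi` so the file cannot carry an inconsistent
#' status.
#'
#' @param path CSV path.
#' @param cutoff positivity cutoff on `marker_fraction` (default 0.30).
#' @return `data.frame` with derived `status` and `npi_group` columns.
#' @export
read_cohort <- function(path, cutoff = 0.30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "marker_fraction", "npi")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df$status <- score_positivity(df$marker_fraction, cutoff = cutoff)
  df$npi_group <- npi_group(df$npi, warn = FALSE)
  df
}

#' Write a cohort table to CSV (UTF-8, header, "." decimal separator)
#' @param cohort data.frame as produced by [gen_cohort()] or [read_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
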