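#' Write a stack as multi-page TIFF with a JSON sidecar
#'
#' Each channel (and, for 3D stacks, each z-plane) is written as one 16-bit
#' grayscale TIFF page; page order is channel-major within z-plane
#' (`z1c1, z1c2, ..., z2c1, ...`). Channel names, array shape and physical
#' pixel size go to a JSON sidecar (`<path>.json`), since baseline TIFF has
#' no portable slot for them. Intensities must lie in `[0, 1]`; they are
#' stored on the 16-bit grid (multiples of 1/65535), so images already
#' quantized to that grid — such as phantoms from [make_phago_phantom_2d()]
#' — round-trip bit-identically.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @seealso [load_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  if (min(stack$data) < 0 || max(stack$data) > 1)
    stop("intensities must lie in [0, 1] for 16-bit TIFF storage")
  nc <- d[length(d)]
  if (length(d) == 4L) {
    pages <- vector("list", d[1] * nc)
    k <- 0L
    for (z in seq_len(d[1])) for (ch in seq_len(nc)) {
      k <- k + 1L
      pages[[k]] <- stack$data[z, , , ch]
    }
  } else {
    pages <- lapply(seq_len(nc), function(ch) stack$data[, , ch])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    channel_names = stack$channel_names,
    shape = d,
    pixel_size_um = stack$pixel_size_um
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multichannel stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any grayscale
#' multi-page TIFF with the same page layout). Channel names and pixel size
#' are taken from the JSON sidecar when present; arguments override it.
#' A missing pixel size (no sidecar and no override) is an error, as is a
#' mismatch between the page count and the channel names.
#'
#' @param path TIFF file path.
#' @param channel_names optional channel names; overrides the sidecar.
#' @param pixel_size_um optional pixel size in micrometres; overrides the
#'   sidecar.
#' @param n_z number of z-planes (pages are channel-major within z). Taken
#'   from the sidecar when present; defaults to 1 (a 2D image) otherwise.
#' @return An [image_stack()].
#' @export
load_stack <- function(path, channel_names = NULL, pixel_size_um = NULL,
                       n_z = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop("multi-sample TIFF pages are not supported; expected grayscale pages")
      p <- p[, , 1]
    }
    unclass(p)
  })
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(channel_names)) channel_names <- meta$channel_names
  if (is.null(channel_names))
    stop("no channel names: none given and no sidecar metadata found")
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop(sprintf("missing pixel size for '%s': no sidecar metadata and no override given", path))
  if (is.null(n_z)) {
    n_z <- if (!is.null(meta$shape) && length(meta$shape) == 4L)
      meta$shape[1] else 1L
  }
  nc <- length(channel_names)
  if (length(pages) != nc * n_z)
    stop(sprintf("channel mismatch: %d TIFF pages but %d channels x %d z-planes expected",
                 length(pages), nc, n_z))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (n_z > 1L) {
    data <- array(0, dim = c(n_z, ny, nx, nc))
    k <- 0L
    for (z in seq_len(n_z)) for (ch in seq_len(nc)) {
      k <- k + 1L
      data[z, , , ch] <- pages[[k]]
    }
  } else {
    data <- array(unlist(pages, use.names = FALSE), dim = c(ny, nx, nc))
  }
  image_stack(data, channel_names, pixel_size_um)
}
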