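#' Multichannel image stack
#'
#' Container for a multichannel fluorescence image, optionally 3D. Data are
#' stored channel-last in R array order: `(y, x, channel)` for 2D images and
#' `(z, y, x, channel)` for z-stacks. Physical pixel size is carried in
#' micrometres: a single value for (isotropic) 2D pixels, or a length-3
#' vector `(z, y, x)` for voxels.
#'
#' @param data numeric array, `(y, x, channel)` or `(z, y, x, channel)`.
#'   All intensities must be finite.
#' @param channel_names character vector naming each channel; length must
#'   equal the size of the last array dimension.
#' @param pixel_size_um physical pixel size in micrometres: one positive
#'   number for 2D, three (`z`, `y`, `x`) for 3D.
#' @return An object of class `ImageStack`: a list with elements `data`,
#'   `channel_names` and `pixel_size_um`.
#' @examples
#' img <- array(runif(4 * 5 * 2), dim = c(4, 5, 2))
#' stk <- image_stack(img, c("tdTomato", "beads"), pixel_size_um = 0.325)
#' stk
#' @export
image_stack <- function(data, channel_names, pixel_size_um) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D (y, x, channel) or 4D (z, y, x, channel) array")
  if (!all(is.finite(data)))
    stop("intensities must be finite")
  nc <- dim(data)[length(dim(data))]
  if (length(channel_names) != nc)
    stop(sprintf("channel mismatch: %d channels in data but %d names given",
                 nc, length(channel_names)))
  is3d <- length(dim(data)) == 4L
  pixel_size_um <- as.numeric(pixel_size_um)
  if (is3d && length(pixel_size_um) != 3L)
    stop("3D stacks need pixel_size_um = c(z, y, x)")
  if (!is3d && length(pixel_size_um) != 1L)
    stop("2D stacks need a single pixel_size_um")
  if (any(!is.finite(pixel_size_um)) || any(pixel_size_um <= 0))
    stop("pixel sizes must be positive")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (length(d) == 4L) "3D" else "2D"
  cat(sprintf("<ImageStack %s> %s px, %d channel(s): %s\n", kind,
              paste(d[-length(d)], collapse = " x "), d[length(d)],
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel size (um): %s\n",
              paste(format(x$pixel_size_um), collapse = " x ")))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

is_3d <- function(stack) length(dim(stack$data)) == 4L

#' Extract one channel from a stack
#'
#' @param stack an [image_stack()].
#' @param channel channel name or integer index.
#' @return A matrix `(y, x)` for 2D stacks or array `(z, y, x)` for 3D.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop(sprintf("no channel named '%s'", channel))
  } else i <- as.integer(channel)
  d <- dim(stack$data)
  if (length(d) == 4L) stack$data[, , , i] else stack$data[, , i]
}
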