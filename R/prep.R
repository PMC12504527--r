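#' Maximum intensity projection
#'
#' Collapses the z axis of a 3D stack by taking, per channel and per (y, x)
#' pixel, the maximum intensity over z. Pixel size metadata keeps its (y, x)
#' components. A 2D input is returned unchanged with a message (projection
#' of an already-projected image is the identity).
#'
#' @param stack an [image_stack()].
#' @return A 2D [image_stack()].
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is_3d(stack)) {
    message("max_intensity_projection: input is already 2D; returning it unchanged")
    return(stack)
  }
  d <- dim(stack$data)
  out <- array(0, dim = d[2:4])
  for (ch in seq_len(d[4]))
    out[, , ch] <- apply(stack$data[, , , ch, drop = FALSE], c(2, 3), max)
  ps <- stack$pixel_size_um[2:3]
  if (ps[1] != ps[2])
    stop("anisotropic (y, x) pixels are not supported in 2D")
  image_stack(out, stack$channel_names, ps[1])
}

#' Per-channel percentile normalization
#'
#' For each channel independently, clips intensities to the `[p_low, p_high]`
#' percentile interval and maps that interval affinely onto `[0, 1]`.
#' Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), the most common convention; the estimator
#' is configurable through `quantile_type`. A channel whose two percentiles
#' coincide (e.g. a constant channel) cannot be normalized and raises an
#' error naming the channel.
#'
#' @param stack an [image_stack()] (2D or 3D).
#' @param low_pct,high_pct percentile bounds, in percent (defaults 1 and 99).
#' @param quantile_type percentile estimator, passed to [stats::quantile()].
#' @return An [image_stack()] with all intensities in `[0, 1]`.
#' @export
percentile_normalize <- function(stack, low_pct = 1, high_pct = 99,
                                 quantile_type = 7) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!(low_pct < high_pct) || low_pct < 0 || high_pct > 100)
    stop("need 0 <= low_pct < high_pct <= 100")
  d <- dim(stack$data)
  nc <- d[length(d)]
  out <- stack$data
  idx <- slice.index(out, length(d))
  for (ch in seq_len(nc)) {
    v <- out[idx == ch]
    q <- quantile(v, c(low_pct, high_pct) / 100, names = FALSE,
                  type = quantile_type)
    if (q[2] <= q[1])
      stop(sprintf(
        "degenerate channel '%s': %g%% and %g%% percentiles coincide (%g)",
        stack$channel_names[ch], low_pct, high_pct, q[1]))
    v <- (pmin(pmax(v, q[1]), q[2]) - q[1]) / (q[2] - q[1])
    out[idx == ch] <- v
  }
  image_stack(out, stack$channel_names, stack$pixel_size_um)
}
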