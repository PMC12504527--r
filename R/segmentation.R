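# Foreground extraction and object labeling: deterministic 2-class K-means
# on scalar intensities (2D assay), thresholding (3D assay), and
# connected-component labeling at configurable connectivity.

#' Deterministic 2-class K-means foreground mask
#'
#' Partitions the pixels of one intensity channel into two clusters by
#' Lloyd's algorithm on scalar intensity, and returns the cluster with the
#' larger centroid as foreground. Initial centroids are pinned at the 1st
#' and 99th percentile intensities, so the segmentation is fully
#' deterministic; assignment ties (a pixel equidistant from both centroids)
#' go to the foreground cluster. Because initialization and updates are
#' affine-equivariant, the mask is invariant to affine rescaling of the
#' channel.
#'
#' @param channel numeric matrix (2D) of intensities; must not be constant.
#' @param tol convergence tolerance on centroid movement (default 1e-6).
#' @param max_iter maximum Lloyd iterations (default 100).
#' @return A logical matrix of the same shape, `TRUE` = foreground.
#' @examples
#' m <- matrix(c(0, 0, 0, 0.9, 0.9), 1)
#' kmeans2_mask(m)
#' @export
kmeans2_mask <- function(channel, tol = 1e-6, max_iter = 100L) {
  if (!is.numeric(channel)) stop("channel must be numeric")
  v <- as.vector(channel)
  if (max(v) == min(v)) stop("cannot cluster a constant channel")
  cen <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  if (cen[1] == cen[2]) cen <- range(v)
  for (it in seq_len(max_iter)) {
    # ties (equidistant) assigned to the upper cluster
    mid <- mean(cen)
    hi <- v >= mid
    new_cen <- c(
      if (any(!hi)) mean(v[!hi]) else cen[1],
      if (any(hi)) mean(v[hi]) else cen[2]
    )
    if (max(abs(new_cen - cen)) < tol) { cen <- new_cen; break }
    cen <- new_cen
  }
  fg <- v >= mean(cen)
  out <- array(fg, dim = dim(channel))
  out
}

#' Label connected components
#'
#' Labels connected foreground components of a binary mask under the stated
#' connectivity (4 or 8 neighbours in 2D; 6 or 26 in 3D). Labels are
#' assigned in order of each component's first pixel in array storage
#' order. An empty mask yields zero objects, not an error.
#'
#' @param mask logical matrix (2D) or 3D logical array.
#' @param connectivity 4 or 8 for 2D masks (default 8), 6 or 26 for 3D
#'   (default 26).
#' @param pixel_size_um optional physical pixel/voxel size carried along
#'   for downstream morphometry.
#' @return An object of class `LabelMap`: list with integer array `labels`,
#'   `n_objects`, `connectivity` and `pixel_size_um`.
#' @export
label_components <- function(mask, connectivity = NULL, pixel_size_um = NULL) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("mask must be logical (or numeric 0/1)")
  nd <- length(dim(mask))
  if (!(nd %in% c(2L, 3L))) stop("mask must be a 2D matrix or 3D array")
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 8L else 26L
  ok <- if (nd == 2L) connectivity %in% c(4L, 8L) else connectivity %in% c(6L, 26L)
  if (!ok)
    stop(sprintf("connectivity %s is invalid for a %dD mask", connectivity, nd))
  mask[is.na(mask)] <- FALSE
  labels <- .cc_label(as.vector(mask), dim(mask), as.integer(connectivity))
  n <- attr(labels, "n_objects")
  attr(labels, "n_objects") <- NULL
  structure(list(labels = labels, n_objects = n,
                 connectivity = as.integer(connectivity),
                 pixel_size_um = pixel_size_um),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("<LabelMap> %s px, %d object(s), connectivity %d\n",
              paste(dim(x$labels), collapse = " x "), x$n_objects,
              x$connectivity))
  invisible(x)
}

#' Threshold segmentation of a 3D channel
#'
#' Voxels at or above `threshold` form the foreground, labeled with
#' 26-connectivity by default. The per-object voxel sets stand in for
#' rendered surfaces in downstream volume and overlap quantification, which
#' is defined over any voxel mask; any alternative segmenter producing a
#' mask can be substituted upstream.
#'
#' @param channel 3D numeric array `(z, y, x)`, normalized to `[0, 1]`.
#' @param threshold intensity threshold in `[0, 1]`.
#' @param connectivity 6 or 26 (default 26).
#' @param voxel_size_um optional `(z, y, x)` voxel size in micrometres.
#' @return A `LabelMap`.
#' @export
segment_channel_3d <- function(channel, threshold = 0.5, connectivity = 26L,
                               voxel_size_um = NULL) {
  if (length(dim(channel)) != 3L) stop("channel must be a 3D array")
  if (threshold < 0 || threshold > 1)
    stop(sprintf("threshold %g outside [0, 1]", threshold))
  label_components(channel >= threshold, connectivity = connectivity,
                   pixel_size_um = voxel_size_um)
}
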