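# 2D bead-engulfment scoring and 3D overlapped-volume quantification.

#' Score bead engulfment for one image
#'
#' A retained cell is engulfing iff at least one of its pixels lies in the
#' bead foreground mask ("non-zero intersection"). The headline statistic
#' is `100 * n_engulfing / n_cells_retained`. An image with no retained
#' cells is an explicit error, never a silent 0.
#'
#' @param records filtered object table from [apply_shape_filters()]; only
#'   rows with `retained = TRUE` are scored.
#' @param labelmap the `LabelMap` the records were measured from.
#' @param bead_mask logical matrix of bead foreground, same shape.
#' @param image_id identifier attached to the result (default `"image"`).
#' @return A list with `cells` (the records, with `n_bead_pixels` and
#'   `engulfing` filled in; non-retained rows are `FALSE` by definition)
#'   and `result`, a one-row data frame (`image_id`, `n_cells_retained`,
#'   `n_engulfing`, `percent_engulfing`).
#' @export
engulfment_fraction <- function(records, labelmap, bead_mask,
                                image_id = "image") {
  stopifnot(inherits(labelmap, "LabelMap"), is.data.frame(records))
  if (is.numeric(bead_mask)) bead_mask <- bead_mask != 0
  if (!identical(dim(labelmap$labels), dim(bead_mask)))
    stop("bead mask and label map shapes differ")
  retained <- records$retained
  if (is.null(retained)) retained <- rep(TRUE, nrow(records))
  if (!any(retained))
    stop(sprintf("no retained cells in image '%s': cannot compute an engulfment percentage", image_id))
  overlap_labels <- labelmap$labels[bead_mask & labelmap$labels > 0]
  n_bead_px <- tabulate(overlap_labels, nbins = labelmap$n_objects)
  records$n_bead_pixels <- n_bead_px[records$label]
  records$engulfing <- retained & records$n_bead_pixels > 0
  n_ret <- sum(retained)
  n_eng <- sum(records$engulfing)
  list(
    cells = records,
    result = data.frame(
      image_id = image_id,
      n_cells_retained = n_ret,
      n_engulfing = n_eng,
      percent_engulfing = 100 * n_eng / n_ret
    )
  )
}

#' Average per-image engulfment percentages per animal
#'
#' Unweighted mean of the per-image percentages within each animal,
#' matching per-animal averaging over the 2-4 images acquired per animal.
#'
#' @param results data frame of per-image results (needs `image_id` and
#'   `percent_engulfing`), e.g. row-bound `result`s from
#'   [engulfment_fraction()].
#' @param image_to_animal data frame mapping `image_id` to `animal_id`;
#'   every image must map to exactly one animal.
#' @return Data frame with `animal_id`, `mean_percent_engulfing`,
#'   `n_images`, ordered by animal id.
#' @export
aggregate_per_animal <- function(results, image_to_animal) {
  stopifnot(is.data.frame(results), is.data.frame(image_to_animal))
  m <- match(results$image_id, image_to_animal$image_id)
  if (anyNA(m))
    stop(sprintf("unmapped image(s): %s",
                 paste(results$image_id[is.na(m)], collapse = ", ")))
  if (anyDuplicated(image_to_animal$image_id))
    stop("image_to_animal maps some image to more than one animal")
  animal <- as.character(image_to_animal$animal_id[m])
  agg <- rowsum(results$percent_engulfing, animal)
  n <- as.vector(table(animal)[rownames(agg)])
  out <- data.frame(
    animal_id = rownames(agg),
    mean_percent_engulfing = as.vector(agg) / n,
    n_images = n
  )
  out[order(out$animal_id), , drop = FALSE]
}

#' Overlapped volume ratio of one object against a reference mask
#'
#' `|object intersect reference| / |object|` on voxel counts; the physical
#' voxel size cancels. Defined for any non-empty voxel set.
#'
#' @param object_mask logical array (the object's voxels).
#' @param reference_mask logical array, same shape.
#' @return A proportion in `[0, 1]`.
#' @export
overlapped_volume_ratio <- function(object_mask, reference_mask) {
  if (is.numeric(object_mask)) object_mask <- object_mask != 0
  if (is.numeric(reference_mask)) reference_mask <- reference_mask != 0
  if (!identical(dim(object_mask), dim(reference_mask)))
    stop("object and reference masks have different shapes")
  v <- sum(object_mask)
  if (v == 0) stop("empty object: overlapped volume ratio is undefined")
  sum(object_mask & reference_mask) / v
}

#' Classify 3D objects by marker overlap
#'
#' For each labeled tdTomato object, computes its volume and its overlapped
#' volume ratio against each marker mask. Objects are included in the
#' analysis iff their DAPI ratio is at least `dapi_threshold` (the nuclear
#' criterion that rejects debris); among included objects, Iba1 positivity
#' requires the Iba1 ratio to reach `marker_threshold`, and P2ry12
#' positivity additionally requires Iba1 positivity (hierarchical gating:
#' a microglia-like object must already carry the pan-myeloid marker).
#'
#' @param objects a 3D `LabelMap` of tdTomato objects.
#' @param channel_masks named list of logical 3D arrays on the same grid;
#'   must contain `DAPI`, `Iba1` and `P2ry12`.
#' @param voxel_size_um voxel size `(z, y, x)` in micrometres; defaults to
#'   the label map's.
#' @param dapi_threshold inclusion threshold on the DAPI ratio (default 0.5).
#' @param marker_threshold positivity threshold for Iba1/P2ry12 ratios
#'   (default 0.5, mirroring the stated DAPI criterion).
#' @return A data frame with one row per object: `object_id`,
#'   `volume_vox`, `volume_um3`, `ratio_dapi`, `ratio_iba1`,
#'   `ratio_p2ry12`, `included`, `iba1_positive`, `p2ry12_positive`.
#' @seealso [summarize_marker_positivity()]
#' @export
classify_objects_3d <- function(objects, channel_masks,
                                voxel_size_um = NULL,
                                dapi_threshold = 0.5,
                                marker_threshold = 0.5) {
  stopifnot(inherits(objects, "LabelMap"))
  need <- c("DAPI", "Iba1", "P2ry12")
  if (!all(need %in% names(channel_masks)))
    stop("channel_masks must contain DAPI, Iba1 and P2ry12")
  labels <- objects$labels
  for (ch in need) {
    if (!identical(dim(channel_masks[[ch]]), dim(labels)))
      stop(sprintf("grid mismatch: %s mask shape differs from the object grid", ch))
  }
  if (is.null(voxel_size_um)) voxel_size_um <- objects$pixel_size_um
  if (is.null(voxel_size_um) || length(voxel_size_um) != 3L)
    stop("voxel_size_um (z, y, x) is required for volumes")
  n <- objects$n_objects
  vol_vox <- tabulate(labels[labels > 0], nbins = n)
  ratio_for <- function(ch) {
    msk <- channel_masks[[ch]]
    if (is.numeric(msk)) msk <- msk != 0
    tabulate(labels[msk & labels > 0], nbins = n) / vol_vox
  }
  rd <- ratio_for("DAPI"); ri <- ratio_for("Iba1"); rp <- ratio_for("P2ry12")
  included <- rd >= dapi_threshold
  iba1_pos <- included & ri >= marker_threshold
  p2_pos <- iba1_pos & rp >= marker_threshold
  data.frame(
    object_id = seq_len(n),
    volume_vox = vol_vox,
    volume_um3 = vol_vox * prod(voxel_size_um),
    ratio_dapi = rd, ratio_iba1 = ri, ratio_p2ry12 = rp,
    included = included, iba1_positive = iba1_pos,
    p2ry12_positive = p2_pos
  )
}

#' Marker-positivity percentages among included objects
#'
#' @param records output of [classify_objects_3d()].
#' @return A list: `n_included`, `percent_iba1` (% of included tdTomato
#'   objects that are Iba1+), `percent_iba1_p2ry12` (% that are both Iba1+
#'   and P2ry12+).
#' @export
summarize_marker_positivity <- function(records) {
  n_inc <- sum(records$included)
  if (n_inc == 0)
    stop("no objects pass the DAPI inclusion criterion")
  list(
    n_included = n_inc,
    percent_iba1 = 100 * sum(records$iba1_positive) / n_inc,
    percent_iba1_p2ry12 = 100 * sum(records$p2ry12_positive) / n_inc
  )
}
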