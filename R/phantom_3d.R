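# Synthetic 3D colocalization phantoms: tdTomato objects placed in a
# 4-channel z-stack, with marker masks (DAPI, Iba1, P2ry12) built so each
# object's voxel-overlap ratio against each marker equals a designed value
# exactly (to the voxel-rounding limit).

#' Configuration for a 3D overlap phantom
#'
#' Each tdTomato object is a solid block of `object_size_vox` voxels; for
#' each marker channel, exactly `round(ratio * volume)` of those voxels are
#' added to the marker mask, so designed overlap ratios are realized to
#' within one voxel's worth of proportion (exactly, when `ratio * volume`
#' is an integer). A small marker-only blob per channel keeps marker masks
#' from being subsets of the object union.
#'
#' @param shape volume shape `(z, y, x)` in voxels.
#' @param voxel_size_um voxel size `(z, y, x)` in micrometres (default
#'   `c(1, 0.325, 0.325)`, a 20x z-stack).
#' @param n_objects number of tdTomato objects.
#' @param dapi_ratios,iba1_ratios,p2ry12_ratios designed per-object overlap
#'   ratios in `[0, 1]`, each of length `n_objects`. Defaults span the
#'   inclusion threshold (DAPI 0.3/0.7/1.0) and both marker-positivity
#'   outcomes.
#' @param object_size_vox voxels per object (a z*y*x block; default
#'   10 x 10 x 10 = 1000).
#' @param background_level,object_intensity background and foreground
#'   intensities on `[0, 1]`.
#' @param noise_sd additive Gaussian noise SD (default 0: noiseless, so
#'   threshold segmentation recovers objects exactly).
#' @param seed integer seed.
#' @return A validated list of class `Overlap3DPhantomConfig`.
#' @export
overlap_phantom_config <- function(shape = c(24L, 96L, 96L),
                                   voxel_size_um = c(1, 0.325, 0.325),
                                   n_objects = 3L,
                                   dapi_ratios = c(0.3, 0.7, 1.0),
                                   iba1_ratios = c(0.9, 0.9, 0.1),
                                   p2ry12_ratios = c(0.0, 0.6, 0.8),
                                   object_size_vox = 1000L,
                                   background_level = 0.05,
                                   object_intensity = 0.8,
                                   noise_sd = 0,
                                   seed = 1L) {
  cfg <- list(shape = as.integer(shape),
              voxel_size_um = as.numeric(voxel_size_um),
              n_objects = as.integer(n_objects),
              dapi_ratios = as.numeric(dapi_ratios),
              iba1_ratios = as.numeric(iba1_ratios),
              p2ry12_ratios = as.numeric(p2ry12_ratios),
              object_size_vox = as.integer(object_size_vox),
              background_level = background_level,
              object_intensity = object_intensity,
              noise_sd = noise_sd, seed = as.integer(seed))
  with(cfg, {
    if (length(shape) != 3 || any(shape < 4)) stop("shape must be (z, y, x), each >= 4")
    if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0))
      stop("voxel_size_um must be 3 positive lengths")
    if (n_objects < 1) stop("n_objects must be >= 1")
    for (r in list(dapi_ratios, iba1_ratios, p2ry12_ratios)) {
      if (length(r) != n_objects)
        stop("each ratio vector must have one entry per object")
      if (any(r < 0 | r > 1)) stop("designed overlap ratios must lie in [0, 1]")
    }
    if (object_size_vox < 8) stop("object_size_vox must be >= 8")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  structure(cfg, class = "Overlap3DPhantomConfig")
}

# block dimensions (z, y, x) for a target voxel count: nearest cube,
# trimmed in x so the count is exact
block_dims <- function(v) {
  s <- max(2L, round(v^(1/3)))
  nz <- s; ny <- s
  nx <- ceiling(v / (nz * ny))
  c(nz, ny, nx)
}

#' Generate a 3D overlap phantom with ground truth
#'
#' Returns a 4-channel z-stack (`tdTomato`, `DAPI`, `Iba1`, `P2ry12`) and a
#' truth table of designed overlap ratios. Objects are non-overlapping
#' blocks; the marker share of each object is the first
#' `round(ratio * volume)` voxels of the block in array storage order.
#'
#' @param config an [overlap_phantom_config()].
#' @return A list with `stack` (an [image_stack()]) and `truth`
#'   (class `PhantomTruth`): an `objects` table (object id, centroid,
#'   volume and designed ratios), the exact `object_labels` array, per-marker
#'   masks, and the config.
#' @export
make_overlap_phantom_3d <- function(config) {
  stopifnot(inherits(config, "Overlap3DPhantomConfig"))
  withr::with_seed(config$seed, make_overlap_phantom_3d_impl(config))
}

make_overlap_phantom_3d_impl <- function(cfg) {
  dm <- cfg$shape
  bd <- block_dims(cfg$object_size_vox)
  if (any(bd + 2 > dm))
    stop(sprintf(
      "object block %s does not fit volume %s: reduce object_size_vox or enlarge shape",
      paste(bd, collapse = "x"), paste(dm, collapse = "x")))

  # non-overlapping block origins on a jittered grid (deterministic layout)
  per_x <- max(1L, (dm[3] - 2L) %/% (bd[3] + 2L))
  per_y <- max(1L, (dm[2] - 2L) %/% (bd[2] + 2L))
  if (per_x * per_y < cfg$n_objects)
    stop(sprintf("volume too small for %d non-overlapping objects", cfg$n_objects))
  labels <- array(0L, dim = dm)
  marker_masks <- list(
    DAPI = array(FALSE, dim = dm),
    Iba1 = array(FALSE, dim = dm),
    P2ry12 = array(FALSE, dim = dm)
  )
  ratios <- list(DAPI = cfg$dapi_ratios, Iba1 = cfg$iba1_ratios,
                 P2ry12 = cfg$p2ry12_ratios)
  obj <- vector("list", cfg$n_objects)
  for (i in seq_len(cfg$n_objects)) {
    gx <- (i - 1L) %% per_x
    gy <- (i - 1L) %/% per_x
    oz <- 2L
    oy <- 2L + gy * (bd[2] + 2L)
    ox <- 2L + gx * (bd[3] + 2L)
    zi <- oz:(oz + bd[1] - 1L)
    yi <- oy:(oy + bd[2] - 1L)
    xi <- ox:(ox + bd[3] - 1L)
    # voxel index list in array storage order, trimmed to the exact count
    vox <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
    vox <- vox[seq_len(cfg$object_size_vox), , drop = FALSE]
    labels[vox] <- i
    v <- nrow(vox)
    for (ch in names(marker_masks)) {
      k <- round(ratios[[ch]][i] * v)
      if (k > 0) marker_masks[[ch]][vox[seq_len(k), , drop = FALSE]] <- TRUE
    }
    obj[[i]] <- data.frame(
      object_id = i, volume_vox = v,
      volume_um3 = v * prod(cfg$voxel_size_um),
      centroid_z = mean(vox[, 1]), centroid_y = mean(vox[, 2]),
      centroid_x = mean(vox[, 3]),
      dapi_ratio = ratios$DAPI[i], iba1_ratio = ratios$Iba1[i],
      p2ry12_ratio = ratios$P2ry12[i]
    )
  }
  # marker-only blobs in the far corner (clear of the object grid rows used)
  blob <- function(arr, z0, y0, x0, s = 3L) {
    zi <- z0:min(dim(arr)[1], z0 + s); yi <- y0:min(dim(arr)[2], y0 + s)
    xi <- x0:min(dim(arr)[3], x0 + s)
    arr[zi, yi, xi] <- TRUE
    arr
  }
  cz <- dm[1] - 4L; cyy <- dm[2] - 4L
  if (cz > max(2L + bd[1], 1L)) {
    marker_masks$DAPI <- blob(marker_masks$DAPI, cz, cyy, 2L)
    marker_masks$Iba1 <- blob(marker_masks$Iba1, cz, cyy, max(2L, dm[3] - 10L))
    marker_masks$P2ry12 <- blob(marker_masks$P2ry12, cz, cyy,
                                max(2L, dm[3] %/% 2))
  }

  img <- array(cfg$background_level, dim = c(dm, 4L))
  img[, , , 1][labels > 0] <- cfg$object_intensity
  img[, , , 2][marker_masks$DAPI] <- cfg$object_intensity
  img[, , , 3][marker_masks$Iba1] <- cfg$object_intensity
  img[, , , 4][marker_masks$P2ry12] <- cfg$object_intensity
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
  img <- quantize16(pmin(pmax(img, 0), 1))

  stack <- image_stack(img, c("tdTomato", "DAPI", "Iba1", "P2ry12"),
                       cfg$voxel_size_um)
  truth <- structure(list(
    objects = do.call(rbind, obj),
    object_labels = labels,
    marker_masks = marker_masks,
    config = cfg
  ), class = "PhantomTruth")
  list(stack = stack, truth = truth)
}
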