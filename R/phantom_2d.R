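# Synthetic 2D phagocytosis phantoms: bright quasi-circular cells (red),
# 2-um bead disks placed inside engulfing cells or far outside all cells
# (blue), nuclei (green), flat background plus Gaussian noise, with exact
# ground truth for every placement.

quantize16 <- function(x) round(x * 65535) / 65535

#' Configuration for a 2D phagocytosis phantom
#'
#' Defaults emulate a 40x field of a bead-injected site: 0.325 um pixels,
#' 200 macrophage-sized cells, 2 um beads, and enough free extracellular
#' beads that the bead channel carries genuine signal mass (so percentile
#' normalization and 2-class K-means behave as they do on real injection
#' sites, where beads are abundant).
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_size_um pixel size in micrometres (isotropic).
#' @param n_cells number of cells (>= 1).
#' @param cell_radius_um_range min/max cell radius in micrometres; must
#'   exceed the bead radius.
#' @param engulfment_fraction fraction of cells that engulf beads, in
#'   `[0, 1]`. The engulfing cell count is `floor(fraction * n_cells + 0.5)`
#'   (round half up), so truth accounting is exact.
#' @param beads_per_engulfing_cell_range min/max beads per engulfing cell
#'   (integers >= 1).
#' @param bead_diameter_um bead diameter in micrometres (default 2, the
#'   standard latex-bead size for in vivo phagocytosis assays).
#' @param n_background_beads free beads placed at least one cell radius
#'   beyond every cell boundary, so they can never count as engulfed.
#' @param background_level flat background intensity in `[0, 1)`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param cell_intensity,bead_intensity,nucleus_intensity foreground
#'   intensities on `[0, 1]` before noise (fixed defaults 0.8 / 0.9 / 0.7).
#' @param boundary_irregularity amplitude of a 5-lobed radial modulation of
#'   the cell boundary, in `[0, 0.5)`. 0 (default) gives circular cells that
#'   pass the circularity filter; large values create lobed cells that fail
#'   it.
#' @param seed integer seed; identical configs give bit-identical phantoms.
#' @return A validated list of class `PhagoPhantomConfig`.
#' @export
phago_phantom_config <- function(image_height_px = 1024L,
                                 image_width_px = 1024L,
                                 pixel_size_um = 0.325,
                                 n_cells = 200L,
                                 cell_radius_um_range = c(3.25, 6.5),
                                 engulfment_fraction = 0.4,
                                 beads_per_engulfing_cell_range = c(1L, 3L),
                                 bead_diameter_um = 2.0,
                                 n_background_beads = 400L,
                                 background_level = 0.1,
                                 noise_sd = 0.02,
                                 cell_intensity = 0.8,
                                 bead_intensity = 0.9,
                                 nucleus_intensity = 0.7,
                                 boundary_irregularity = 0,
                                 seed = 1L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    cell_radius_um_range = as.numeric(cell_radius_um_range),
    engulfment_fraction = engulfment_fraction,
    beads_per_engulfing_cell_range = as.integer(beads_per_engulfing_cell_range),
    bead_diameter_um = bead_diameter_um,
    n_background_beads = as.integer(n_background_beads),
    background_level = background_level,
    noise_sd = noise_sd,
    cell_intensity = cell_intensity,
    bead_intensity = bead_intensity,
    nucleus_intensity = nucleus_intensity,
    boundary_irregularity = boundary_irregularity,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (engulfment_fraction < 0 || engulfment_fraction > 1)
      stop("engulfment_fraction must lie in [0, 1]")
    if (bead_diameter_um <= 0) stop("bead_diameter_um must be positive")
    if (n_cells < 1) stop("n_cells must be >= 1")
    if (length(cell_radius_um_range) != 2 ||
        cell_radius_um_range[1] > cell_radius_um_range[2] ||
        cell_radius_um_range[1] <= bead_diameter_um / 2)
      stop("cell radii must be an increasing range exceeding the bead radius")
    if (any(beads_per_engulfing_cell_range < 1) ||
        beads_per_engulfing_cell_range[1] > beads_per_engulfing_cell_range[2])
      stop("beads_per_engulfing_cell_range must be increasing integers >= 1")
    if (background_level < 0 || background_level >= 1)
      stop("background_level must lie in [0, 1)")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (boundary_irregularity < 0 || boundary_irregularity >= 0.5)
      stop("boundary_irregularity must lie in [0, 0.5)")
    if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
    # coarse capacity check: cells as (2 r_max + gap)^2 tiles must fit in
    # half the field, otherwise random placement will stall
    rmax_px <- cell_radius_um_range[2] / pixel_size_um
    need <- n_cells * (2 * rmax_px + 3)^2
    if (need > 0.5 * image_height_px * image_width_px)
      stop(sprintf(
        "image too small for n_cells = %d at max radius %.1f px: need ~%.0f px^2 free, have %d (cell density too high)",
        n_cells, rmax_px, need / 0.5, image_height_px * image_width_px))
  })
  structure(cfg, class = "PhagoPhantomConfig")
}

# disk membership on the pixel grid, with optional 5-lobed boundary
# modulation; returns an index matrix of (y, x) pixels inside
disk_pixels <- function(cy, cx, r, ny, nx, irregularity = 0, phase = 0) {
  ylo <- max(1L, floor(cy - r * (1 + irregularity)))
  yhi <- min(ny, ceiling(cy + r * (1 + irregularity)))
  xlo <- max(1L, floor(cx - r * (1 + irregularity)))
  xhi <- min(nx, ceiling(cx + r * (1 + irregularity)))
  ys <- ylo:yhi; xs <- xlo:xhi
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  d2 <- dy^2 + dx^2
  if (irregularity > 0) {
    theta <- atan2(dy, dx)
    reff <- r * (1 + irregularity * cos(5 * theta + phase))
    inside <- d2 <= reff^2
  } else {
    inside <- d2 <= r^2
  }
  w <- which(inside, arr.ind = TRUE)
  cbind(y = ys[w[, 1]], x = xs[w[, 2]])
}

#' Generate a 2D phagocytosis phantom with ground truth
#'
#' Renders a 3-channel 2D image (`tdTomato` = cells, `beads`, `nuclei`) plus
#' an exact truth record. Cells are non-overlapping disks; each engulfing
#' cell contains 1 or more beads fully inside its boundary; free beads sit
#' at least one cell radius beyond every cell boundary, so engulfment
#' ground truth is unambiguous under "any shared pixel" scoring. Additive
#' Gaussian noise is applied last and the image is clipped to `[0, 1]` and
#' quantized to the 16-bit grid (the storage precision of [write_stack()]).
#'
#' @param config a [phago_phantom_config()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `PhantomTruth`): `cells` and `beads` placement tables,
#'   `true_engulfment_fraction`, and exact `cell_mask` / `bead_mask` /
#'   `nucleus_mask` logical matrices.
#' @examples
#' ph <- make_phago_phantom_2d(phago_phantom_config(
#'   image_height_px = 256, image_width_px = 256, n_cells = 10,
#'   n_background_beads = 25, engulfment_fraction = 0.4, seed = 1))
#' sum(ph$truth$cells$engulfs) # exactly 4
#' @export
make_phago_phantom_2d <- function(config) {
  stopifnot(inherits(config, "PhagoPhantomConfig"))
  withr::with_seed(config$seed, make_phago_phantom_2d_impl(config))
}

make_phago_phantom_2d_impl <- function(cfg) {
  ny <- cfg$image_height_px; nx <- cfg$image_width_px
  ps <- cfg$pixel_size_um
  r_bead <- cfg$bead_diameter_um / 2 / ps
  gap <- 3 # min boundary gap in px, keeps 8-connected components separate

  # --- place cells (rejection sampling, bounded retries) ---
  radii_px <- runif(cfg$n_cells, cfg$cell_radius_um_range[1],
                    cfg$cell_radius_um_range[2]) / ps
  cy <- numeric(cfg$n_cells); cx <- numeric(cfg$n_cells)
  max_tries <- 2000L * cfg$n_cells
  tries <- 0L
  for (i in seq_len(cfg$n_cells)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf(
          "could not place %d non-overlapping cells after %d tries: cell density too high for the image size",
          cfg$n_cells, max_tries))
      m <- radii_px[i] * (1 + cfg$boundary_irregularity) + 2
      y <- runif(1, m, ny - m); x <- runif(1, m, nx - m)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      ok <- all((y - cy[j])^2 + (x - cx[j])^2 >
                  (radii_px[i] + radii_px[j] + gap)^2)
      if (ok) break
    }
    cy[i] <- y; cx[i] <- x
  }

  # --- engulfment assignment: round half up ---
  n_eng <- floor(cfg$engulfment_fraction * cfg$n_cells + 0.5)
  engulfs <- rep(FALSE, cfg$n_cells)
  if (n_eng > 0) engulfs[sample.int(cfg$n_cells, n_eng)] <- TRUE

  # --- beads inside engulfing cells (fully inside the disk) ---
  bead_y <- numeric(0); bead_x <- numeric(0); bead_cell <- integer(0)
  n_beads_per_cell <- integer(cfg$n_cells)
  rng <- cfg$beads_per_engulfing_cell_range
  for (i in which(engulfs)) {
    nb <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    placed_y <- numeric(0); placed_x <- numeric(0)
    rmax <- radii_px[i] * (1 - cfg$boundary_irregularity) - r_bead - 1
    for (b in seq_len(nb)) {
      for (try in 1:50) {
        a <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * max(rmax, 0.5)
        by <- cy[i] + rr * sin(a); bx <- cx[i] + rr * cos(a)
        sep <- all((by - placed_y)^2 + (bx - placed_x)^2 > (2 * r_bead)^2)
        if (sep || try == 50L) break
      }
      placed_y <- c(placed_y, by); placed_x <- c(placed_x, bx)
    }
    bead_y <- c(bead_y, placed_y); bead_x <- c(bead_x, placed_x)
    bead_cell <- c(bead_cell, rep(i, nb))
    n_beads_per_cell[i] <- nb
  }

  # --- free beads, >= 1 cell radius beyond every cell boundary ---
  n_free <- cfg$n_background_beads
  if (n_free > 0) {
    fy <- numeric(n_free); fx <- numeric(n_free)
    placed <- 0L; tries <- 0L
    while (placed < n_free) {
      tries <- tries + 1L
      if (tries > 2000L * n_free)
        stop("could not place background beads clear of all cells: field too crowded")
      y <- runif(1, r_bead + 1, ny - r_bead - 1)
      x <- runif(1, r_bead + 1, nx - r_bead - 1)
      clear <- all((y - cy)^2 + (x - cx)^2 > (2 * radii_px + r_bead)^2)
      if (!clear) next
      if (placed > 0) {
        jj <- seq_len(placed)
        if (!all((y - fy[jj])^2 + (x - fx[jj])^2 > (2 * r_bead)^2)) next
      }
      placed <- placed + 1L
      fy[placed] <- y; fx[placed] <- x
    }
    bead_y <- c(bead_y, fy); bead_x <- c(bead_x, fx)
    bead_cell <- c(bead_cell, rep(NA_integer_, n_free))
  }

  # --- rasterize masks ---
  cell_mask <- matrix(FALSE, ny, nx)
  nucleus_mask <- matrix(FALSE, ny, nx)
  phases <- runif(cfg$n_cells, 0, 2 * pi)
  for (i in seq_len(cfg$n_cells)) {
    px <- disk_pixels(cy[i], cx[i], radii_px[i], ny, nx,
                      cfg$boundary_irregularity, phases[i])
    cell_mask[px] <- TRUE
    npx <- disk_pixels(cy[i], cx[i], 0.45 * radii_px[i], ny, nx)
    nucleus_mask[npx] <- TRUE
  }
  bead_mask <- matrix(FALSE, ny, nx)
  for (b in seq_along(bead_y))
    bead_mask[disk_pixels(bead_y[b], bead_x[b], r_bead, ny, nx)] <- TRUE

  # --- compose channels, add noise, clip, quantize to storage grid ---
  img <- array(cfg$background_level, dim = c(ny, nx, 3))
  img[, , 1][cell_mask] <- cfg$cell_intensity
  img[, , 2][bead_mask] <- cfg$bead_intensity
  img[, , 3][nucleus_mask] <- cfg$nucleus_intensity
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
  img <- quantize16(pmin(pmax(img, 0), 1))

  stack <- image_stack(img, c("tdTomato", "beads", "nuclei"), ps)
  cells <- data.frame(
    cell_id = seq_len(cfg$n_cells),
    center_y_px = cy, center_x_px = cx,
    radius_px = radii_px, radius_um = radii_px * ps,
    engulfs = engulfs, n_beads = n_beads_per_cell
  )
  beads <- data.frame(
    bead_id = seq_along(bead_y), y_px = bead_y, x_px = bead_x,
    cell_id = bead_cell
  )
  truth <- structure(list(
    cells = cells, beads = beads,
    true_engulfment_fraction = n_eng / cfg$n_cells,
    cell_mask = cell_mask, bead_mask = bead_mask,
    nucleus_mask = nucleus_mask, config = cfg
  ), class = "PhantomTruth")
  list(stack = stack, truth = truth)
}

#' Write a phantom to disk (image + truth CSVs + config JSON)
#'
#' @param phantom result of [make_phago_phantom_2d()] or
#'   [make_overlap_phantom_3d()].
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(phantom$stack, file.path(dir, paste0(name, ".tif")))
  tr <- phantom$truth
  if (!is.null(tr$cells))
    write.csv(tr$cells, file.path(dir, paste0(name, "_cells.csv")),
              row.names = FALSE)
  if (!is.null(tr$beads))
    write.csv(tr$beads, file.path(dir, paste0(name, "_beads.csv")),
              row.names = FALSE)
  if (!is.null(tr$objects))
    write.csv(tr$objects, file.path(dir, paste0(name, "_objects.csv")),
              row.names = FALSE)
  cfg <- tr$config
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(dir, paste0(name, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
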