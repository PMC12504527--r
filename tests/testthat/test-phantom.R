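test_that("engulfing cell count rounds half-up from the configured fraction", {
  ph <- small_phantom_2d(frac = 0.4, n_cells = 10)
  expect_identical(sum(ph$truth$cells$engulfs), 4L)
  ph2 <- small_phantom_2d(frac = 0.25, n_cells = 6) # 1.5 -> 2
  expect_identical(sum(ph2$truth$cells$engulfs), 2L)
  expect_equal(ph2$truth$true_engulfment_fraction, 2 / 6)
  # truth-file consistency
  expect_equal(mean(ph$truth$cells$engulfs), ph$truth$true_engulfment_fraction)
  expect_lte(abs(mean(ph$truth$cells$engulfs) - 0.4), 1 / 10)
})

test_that("identical configs give bit-identical phantoms", {
  a <- small_phantom_2d(seed = 11)
  b <- small_phantom_2d(seed = 11)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- small_phantom_2d(seed = 12)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("beads of engulfing cells lie fully inside the cell disk", {
  ph <- small_phantom_2d(frac = 0.6, seed = 4)
  tr <- ph$truth
  r_bead <- tr$config$bead_diameter_um / 2 / tr$config$pixel_size_um
  eng <- tr$beads[!is.na(tr$beads$cell_id), ]
  expect_gt(nrow(eng), 0)
  for (i in seq_len(nrow(eng))) {
    cl <- tr$cells[eng$cell_id[i], ]
    d <- sqrt((eng$y_px[i] - cl$center_y_px)^2 + (eng$x_px[i] - cl$center_x_px)^2)
    expect_lte(d + r_bead, cl$radius_px)
  }
})

test_that("with zero engulfment no bead pixel touches any cell", {
  ph <- small_phantom_2d(frac = 0, seed = 5)
  expect_identical(sum(ph$truth$cells$engulfs), 0L)
  expect_false(any(ph$truth$bead_mask & ph$truth$cell_mask))
})

test_that("noiseless zero-background phantoms are piecewise constant", {
  ph <- small_phantom_2d(noise_sd = 0, background_level = 0, seed = 2)
  vals <- sort(unique(as.vector(ph$stack$data)))
  q <- function(x) round(x * 65535) / 65535
  expect_true(all(vals %in% q(c(0, 0.7, 0.8, 0.9))))
})

test_that("impossible cell densities raise a placement error", {
  expect_error(
    phago_phantom_config(image_height_px = 128, image_width_px = 128,
                         n_cells = 200),
    "density")
})

test_that("config invariants are enforced", {
  expect_error(phago_phantom_config(engulfment_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phago_phantom_config(bead_diameter_um = 0), "positive")
  expect_error(phago_phantom_config(cell_radius_um_range = c(0.5, 0.8)),
               "bead radius")
  expect_error(phago_phantom_config(n_cells = 0), "n_cells")
})

test_that("3D phantom realizes designed overlap counts exactly", {
  ph <- make_overlap_phantom_3d(overlap_phantom_config(
    dapi_ratios = c(0.7, 0.0, 1.0), iba1_ratios = c(0.9, 0.9, 0.1),
    p2ry12_ratios = c(0.25, 0.5, 1.0)))
  tr <- ph$truth
  for (i in 1:3) {
    obj <- tr$object_labels == i
    v <- sum(obj)
    expect_identical(v, 1000L)
    expect_identical(sum(obj & tr$marker_masks$DAPI),
                     as.integer(round(tr$objects$dapi_ratio[i] * v)))
    expect_identical(sum(obj & tr$marker_masks$Iba1),
                     as.integer(round(tr$objects$iba1_ratio[i] * v)))
    expect_identical(sum(obj & tr$marker_masks$P2ry12),
                     as.integer(round(tr$objects$p2ry12_ratio[i] * v)))
  }
  # ratio 0 -> disjoint; ratio 1 -> object subset of marker mask
  expect_false(any(tr$object_labels == 2 & tr$marker_masks$DAPI))
  expect_true(all(tr$marker_masks$DAPI[tr$object_labels == 3]))
})

test_that("3D phantom is deterministic and validates its config", {
  a <- make_overlap_phantom_3d(overlap_phantom_config(noise_sd = 0.01, seed = 3))
  b <- make_overlap_phantom_3d(overlap_phantom_config(noise_sd = 0.01, seed = 3))
  expect_identical(a$stack$data, b$stack$data)
  expect_error(overlap_phantom_config(dapi_ratios = c(0.5, 1.2, 0)), "\\[0, 1\\]")
  expect_error(overlap_phantom_config(iba1_ratios = c(0.5, 0.5)),
               "one entry per object")
  expect_error(
    make_overlap_phantom_3d(overlap_phantom_config(
      shape = c(12L, 20L, 20L), n_objects = 12L,
      dapi_ratios = rep(0.5, 12), iba1_ratios = rep(0.5, 12),
      p2ry12_ratios = rep(0.5, 12))),
    "too small")
})
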