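# build a label map of n_cells 3x3 squares in a row plus a bead mask
# touching the first n_touch of them
grid_cells <- function(n_cells, n_touch) {
  m <- matrix(FALSE, 7, 5 * n_cells + 2)
  for (i in seq_len(n_cells)) m[3:5, (5 * i - 3):(5 * i - 1)] <- TRUE
  lm <- label_components(m, 8, pixel_size_um = 1)
  beads <- matrix(FALSE, 7, 5 * n_cells + 2)
  for (i in seq_len(n_touch)) beads[4, 5 * i - 2] <- TRUE
  recs <- apply_shape_filters(measure_regions(lm),
                              circ_min = 0, diam_range_um = c(0, Inf))
  list(lm = lm, beads = beads, recs = recs)
}

test_that("engulfment is any non-zero cell/bead intersection", {
  g <- grid_cells(10, 4)
  sc <- engulfment_fraction(g$recs, g$lm, g$beads, image_id = "im1")
  expect_identical(sc$result$n_cells_retained, 10L)
  expect_identical(sc$result$n_engulfing, 4L)
  expect_equal(sc$result$percent_engulfing, 40)
  expect_identical(sum(sc$cells$engulfing), 4L)
  # disjoint beads -> 0%
  sc0 <- engulfment_fraction(g$recs, g$lm, matrix(FALSE, 7, 52))
  expect_equal(sc0$result$percent_engulfing, 0)
})

test_that("an image with no retained cells is an explicit error", {
  g <- grid_cells(3, 1)
  g$recs$retained <- FALSE
  expect_error(engulfment_fraction(g$recs, g$lm, g$beads), "no retained cells")
  expect_error(engulfment_fraction(g$recs[0, ], g$lm, g$beads),
               "no retained cells")
})

test_that("adding a bead pixel on a cell weakly increases the percentage", {
  g <- grid_cells(6, 2)
  base <- engulfment_fraction(g$recs, g$lm, g$beads)$result$percent_engulfing
  more <- g$beads; more[4, 5 * 4 - 2] <- TRUE # bead on a new cell
  after <- engulfment_fraction(g$recs, g$lm, more)$result$percent_engulfing
  expect_gte(after, base)
  # on an already-engulfing cell: unchanged
  dup <- g$beads; dup[3, 5 * 1 - 3] <- TRUE
  expect_equal(engulfment_fraction(g$recs, g$lm, dup)$result$percent_engulfing,
               base)
})

test_that("per-animal aggregation is the unweighted mean of image percentages", {
  res <- data.frame(image_id = c("i1", "i2", "i3"),
                    percent_engulfing = c(40, 60, 10))
  map <- data.frame(image_id = c("i1", "i2", "i3"),
                    animal_id = c("m1", "m1", "m2"))
  agg <- aggregate_per_animal(res, map)
  expect_equal(agg$mean_percent_engulfing[agg$animal_id == "m1"], 50)
  expect_equal(agg$mean_percent_engulfing[agg$animal_id == "m2"], 10)
  # permuting image order changes nothing
  agg2 <- aggregate_per_animal(res[c(3, 1, 2), ], map)
  expect_equal(agg, agg2)
  expect_error(aggregate_per_animal(
    data.frame(image_id = "iX", percent_engulfing = 1), map), "unmapped")
})

test_that("overlapped volume ratio counts shared voxels over object voxels", {
  obj <- array(FALSE, dim = c(10, 10, 10)); obj[1:10, 1:10, 1:10] <- TRUE
  expect_equal(overlapped_volume_ratio(obj, obj), 1)
  none <- array(FALSE, dim = c(10, 10, 10))
  expect_equal(overlapped_volume_ratio(obj, none), 0)
  ref <- array(FALSE, dim = c(10, 10, 10)); ref[1:7, , ] <- TRUE # 700 voxels
  expect_equal(overlapped_volume_ratio(obj, ref), 0.7)
  expect_error(overlapped_volume_ratio(none, obj), "empty object")
  expect_error(overlapped_volume_ratio(obj, array(FALSE, dim = c(5, 5, 5))),
               "shapes")
})

test_that("3D classification applies DAPI inclusion and hierarchical gating", {
  ph <- make_overlap_phantom_3d(overlap_phantom_config(
    dapi_ratios = c(0.49, 0.5, 1.0), iba1_ratios = c(0.9, 0.9, 0.1),
    p2ry12_ratios = c(0.9, 0.6, 0.9)))
  lm <- segment_channel_3d(get_channel(ph$stack, "tdTomato"), 0.5,
                           voxel_size_um = ph$stack$pixel_size_um)
  recs <- classify_objects_3d(lm, ph$truth$marker_masks)
  expect_identical(recs$included, c(FALSE, TRUE, TRUE)) # 0.49 just misses
  expect_identical(recs$iba1_positive, c(FALSE, TRUE, FALSE))
  # object 3 has high P2ry12 but is Iba1-negative: hierarchical gate blocks it
  expect_identical(recs$p2ry12_positive, c(FALSE, TRUE, FALSE))
  expect_true(all(!recs$p2ry12_positive | recs$iba1_positive))
  sm <- summarize_marker_positivity(recs)
  expect_equal(sm$percent_iba1, 50)
  expect_equal(sm$percent_iba1_p2ry12, 50)
})

test_that("volumes use the physical voxel size", {
  lab <- array(0L, dim = c(10, 10, 10)); lab[1:10, 1:10, 1:10] <- 1L
  lm <- structure(list(labels = lab, n_objects = 1L, connectivity = 26L,
                       pixel_size_um = c(0.5, 0.5, 0.5)),
                  class = "LabelMap")
  masks <- list(DAPI = lab > 0, Iba1 = lab > 0, P2ry12 = lab > 0)
  recs <- classify_objects_3d(lm, masks)
  expect_equal(recs$volume_um3, 125) # 1000 voxels x 0.125 um^3
  bad <- list(DAPI = array(FALSE, c(5, 5, 5)), Iba1 = lab > 0, P2ry12 = lab > 0)
  expect_error(classify_objects_3d(lm, bad), "grid mismatch")
})
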