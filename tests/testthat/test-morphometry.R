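test_that("circularity index matches direct evaluation of the formula", {
  # frozen direct evaluations of (4*pi*A/P^2) * (1 - 0.5/r)^2, r = P/(2*pi) + 0.5
  expect_equal(circularity_index(100, 40), 0.6751768, tolerance = 1e-6)
  expect_equal(circularity_index(314.159, 62.832), 0.9070247, tolerance = 1e-6)
  expect_equal(circularity_index(pi, 2 * pi), 4 / 9, tolerance = 1e-12)
  # formula identity on a grid, to numerical precision
  grid <- expand.grid(A = c(1, 10, 100, 1000, 12345), P = c(4, 10, 36, 400))
  direct <- with(grid, {
    r <- P / (2 * pi) + 0.5
    (4 * pi * A / P^2) * (1 - 0.5 / r)^2
  })
  expect_equal(circularity_index(grid$A, grid$P), direct, tolerance = 1e-12)
  expect_error(circularity_index(0, 10), "positive")
  expect_error(circularity_index(10, -1), "positive")
})

test_that("digitization correction vanishes at large scale", {
  A <- 100; P <- 40
  ks <- c(1, 10, 100, 1e4)
  vals <- circularity_index(A * ks^2, P * ks)
  lim <- 4 * pi * A / P^2
  expect_true(all(diff(abs(vals - lim)) < 0))
  expect_equal(vals[4], lim, tolerance = 1e-3)
})

test_that("region measurement reproduces known geometry", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  lm <- label_components(sq, 8, pixel_size_um = 0.5)
  r <- measure_regions(lm)
  expect_identical(r$area_px, 100L)
  expect_equal(r$area_um2, 25)
  expect_equal(r$equivalent_diameter_um, 2 * sqrt(25 / pi), tolerance = 1e-12)
  expect_equal(r$perimeter_px, 36)   # chain estimator
  expect_equal(measure_regions(lm, perimeter = "crack")$perimeter_px, 40)
  expect_equal(r$centroid_y, 7.5)
  expect_equal(r$centroid_x, 7.5)
})

test_that("degenerate and multiple objects are measured sanely", {
  m <- matrix(FALSE, 6, 12); m[2, 2] <- TRUE; m[4:5, 8:9] <- TRUE
  r <- measure_regions(label_components(m, 8, pixel_size_um = 1))
  expect_identical(nrow(r), 2L)
  expect_identical(r$label, 1:2)
  expect_identical(r$area_px, c(1L, 4L))
  expect_true(all(r$perimeter_px > 0))
  expect_error(measure_regions(label_components(m, 8), pixel_size_um = c(1, 2)),
               "anisotropic")
  empty <- measure_regions(label_components(matrix(FALSE, 3, 3)),
                           pixel_size_um = 1)
  expect_identical(nrow(empty), 0L)
})

test_that("digitized disks pass the 0.7 filter and thin bars fail", {
  for (r in 5:15) {
    rec <- measure_regions(label_components(disk_mask(r), 8, pixel_size_um = 1))
    expect_gte(rec$circularity, 0.7)
  }
  for (len in c(10, 15, 25, 40)) {
    rec <- measure_regions(label_components(bar_mask(len), 8, pixel_size_um = 1))
    expect_lt(rec$circularity, 0.7)
  }
})

test_that("shape filters use strict exclusion below 0.7 and a 5-20 um window", {
  recs <- data.frame(
    label = 1:5,
    area_px = 100, area_um2 = 50,
    perimeter_px = 40,
    equivalent_diameter_um = c(10, 10, 4.9, 5.0, 20.0),
    circularity = c(0.69, 0.70, 0.9, 0.9, 0.9),
    centroid_y = 0, centroid_x = 0
  )
  out <- apply_shape_filters(recs)
  expect_identical(out$retained, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(out$passes_circularity, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(out$passes_size, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  aud <- filter_audit(out)
  expect_identical(aud$n_excluded_circularity, 1L)
  expect_identical(aud$n_excluded_size, 1L)
  expect_identical(aud$n_retained, 3L)
})

test_that("filters are idempotent and order-independent", {
  set.seed(51)
  recs <- data.frame(
    label = 1:20, area_px = 100,
    area_um2 = runif(20, 5, 400),
    perimeter_px = 40,
    equivalent_diameter_um = runif(20, 2, 30),
    circularity = runif(20, 0.3, 1.1),
    centroid_y = 0, centroid_x = 0
  )
  once <- apply_shape_filters(recs)
  twice <- apply_shape_filters(once)
  expect_identical(once$retained, twice$retained)
  shuffled <- apply_shape_filters(recs[sample(20), ])
  expect_identical(shuffled$retained[order(shuffled$label)],
                   once$retained[order(once$label)])
})

test_that("area mode filters on cross-sectional area instead", {
  recs <- data.frame(label = 1:2, area_px = c(10, 100),
                     area_um2 = c(4, 12), perimeter_px = 20,
                     equivalent_diameter_um = c(2.3, 3.9),
                     circularity = 0.9, centroid_y = 0, centroid_x = 0)
  out <- apply_shape_filters(recs, size_mode = "area")
  expect_identical(out$passes_size, c(FALSE, TRUE))
})
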