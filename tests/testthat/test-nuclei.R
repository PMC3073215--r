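make_disc_image <- function(size, centers, radius, value = 0.8) {
  m <- matrix(0, size, size)
  for (ct in centers) m <- draw_disc(m, ct, radius, value)
  m
}

test_that("well-separated bright discs are segmented one-to-one", {
  blue <- make_disc_image(200, list(c(50, 50), c(50, 150), c(150, 100)), 20)
  nuc <- segment_nuclei(blue)
  expect_equal(nrow(nuc$features), 3L)
  expect_equal(sort(unique(as.vector(nuc$labels))), 0:3)
  # connected-components oracle on the thresholded fixture
  cc <- EBImage::bwlabel(blue > 0.4)
  expect_equal(max(cc), 3)
  # relabelling follows raster order of centroids
  expect_equal(order(nuc$features$centroid_row), seq_len(3))

  # K = n for n separated discs
  for (n in c(1, 4, 6)) {
    centers <- lapply(seq_len(n), function(i) {
      c(40 + 55 * ((i - 1) %/% 3), 40 + 60 * ((i - 1) %% 3))
    })
    b <- make_disc_image(220, centers, 18)
    expect_equal(nrow(segment_nuclei(b)$features), n)
  }
})

test_that("blank images yield an empty map with a warning, not an error", {
  expect_warning(nuc <- segment_nuclei(matrix(0, 50, 50)), "no foreground")
  expect_equal(nrow(nuc$features), 0L)
  expect_true(all(nuc$labels == 0L))
  expect_warning(segment_nuclei(matrix(0.5, 50, 50)), "no foreground")
})

test_that("watershed separates touching discs and preserves the mask", {
  # two discs overlapping by ~30% of the radius
  blue <- make_disc_image(140, list(c(70, 50), c(70, 78)), 20)
  nuc <- segment_nuclei(blue, segmentation_params(min_solidity = 0.8))
  expect_equal(nrow(nuc$features), 2L)

  # distance-transform peak oracle: the dumbbell has two h-maxima
  mask <- make_disc_image(140, list(c(70, 50), c(70, 78)), 20, value = 1)
  labs <- watershed_split(mask, h = 2)
  expect_equal(max(labs), 2L)
  expect_true(all((labs > 0) == (mask > 0))) # partition property

  # a single disc passes through as one label with identical support
  one <- make_disc_image(80, list(c(40, 40)), 18, value = 1)
  l1 <- watershed_split(one, h = 2)
  expect_equal(max(l1), 1L)
  expect_true(all((l1 > 0) == (one > 0)))

  expect_equal(max(watershed_split(matrix(0, 30, 30), h = 1)), 0L)
})

test_that("watershed partitions random blob masks without inventing pixels", {
  set.seed(61)
  for (t in 1:5) {
    m <- matrix(0, 120, 120)
    for (b in 1:4) {
      m <- draw_disc(m, c(runif(1, 20, 100), runif(1, 20, 100)),
                     runif(1, 8, 16), 1)
    }
    labs <- watershed_split(m, h = 1.5)
    expect_true(all((labs > 0) == (m > 0)))
  }
})

test_that("shape and size gates remove non-nuclei and relabel survivors", {
  labels <- matrix(0L, 120, 120)
  labels <- draw_disc(labels, c(40, 40), 18, 1L)     # good nucleus
  labels[100, 100] <- 2L; labels[100, 101] <- 2L      # 2-px speck
  labels <- draw_disc(labels, c(80, 90), 12, 3L)      # second good nucleus
  labels[1, 60] <- 4L                                 # border pixel object
  p <- segmentation_params(min_area = 200)
  nuc <- filter_objects(labels, p)
  # speck (area 2) and border object removed; both discs retained
  expect_equal(nrow(nuc$features), 2L)
  expect_equal(nuc$features$label_id, c(1L, 2L))
  expect_true(all(!nuc$features$touches_border))

  # a solid disc has solidity ~ 1 and survives a 0.9 gate
  solid <- matrix(0L, 80, 80)
  solid <- draw_disc(solid, c(40, 40), 20, 1L)
  f <- fishdots:::region_features(solid)
  expect_gt(f$solidity, 0.95)
  expect_equal(nrow(filter_objects(solid, segmentation_params(
    min_area = 200, min_solidity = 0.9))$features), 1L)

  # a plus-shaped (non-convex) object fails the same gate
  plus <- matrix(0L, 90, 90)
  plus[40:50, 15:75] <- 1L
  plus[15:75, 40:50] <- 1L
  expect_lt(fishdots:::region_features(plus)$solidity, 0.7)
  expect_equal(nrow(filter_objects(plus, segmentation_params(
    min_area = 200, min_solidity = 0.9))$features), 0L)

  # an elongated bar fails the eccentricity gate
  bar <- matrix(0L, 100, 100)
  bar[45:50, 10:90] <- 1L
  expect_equal(nrow(filter_objects(bar, segmentation_params(
    min_area = 100, max_eccentricity = 0.95))$features), 0L)

  # a disc clipped by the image border is removed
  clipped <- matrix(0L, 80, 80)
  clipped <- draw_disc(clipped, c(3, 40), 15, 1L)
  expect_equal(nrow(filter_objects(clipped, segmentation_params(
    min_area = 100))$features), 0L)
})

test_that("raising min_area never increases the nucleus count", {
  blue <- make_disc_image(220, list(c(50, 50), c(50, 150), c(150, 60),
                                    c(160, 160)), 16)
  blue <- draw_disc(blue, c(110, 110), 9, 0.8)
  ks <- sapply(c(100, 400, 700, 1200), function(am) {
    nrow(segment_nuclei(blue, segmentation_params(min_area = am))$features)
  })
  expect_true(all(diff(ks) <= 0))
})

test_that("segmentation is deterministic", {
  blue <- make_disc_image(150, list(c(50, 50), c(100, 100)), 20)
  blue <- blue + matrix(seq(0, 0.05, length.out = 150^2), 150, 150)
  a <- segment_nuclei(blue)
  b <- segment_nuclei(blue)
  expect_identical(a$labels, b$labels)
  expect_identical(a$features, b$features)
})

test_that("DAPI QC flags empty or dim blue channels", {
  blank <- matrix(0, 100, 100)
  suppressWarnings(m0 <- segment_nuclei(blank))
  qc0 <- qc_dapi(blank, m0)
  expect_true(qc0$no_dapi_suspected)
  expect_equal(qc0$nuclear_area_fraction, 0)

  dim_blue <- matrix(0.02, 100, 100)
  suppressWarnings(m1 <- segment_nuclei(dim_blue))
  expect_true(qc_dapi(dim_blue, m1)$no_dapi_suspected) # intensity floor

  # three bright discs covering ~10% of the area pass
  blue <- make_disc_image(200, list(c(50, 50), c(50, 150), c(150, 100)), 21)
  nuc <- segment_nuclei(blue)
  qc <- qc_dapi(blue, nuc)
  expect_false(qc$no_dapi_suspected)
  expect_equal(qc$nuclear_area_fraction, sum(blue > 0.4) / 200^2,
               tolerance = 0.02)
})
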