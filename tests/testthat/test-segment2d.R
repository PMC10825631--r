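test_that("default strip rectangles on a 512x512 plane match the tuned geometry", {
  rect <- strip_rectangles(512, 512)
  left <- rect[rect$side == "left", ]
  right <- rect[rect$side == "right", ]
  expect_identical(c(left$col_min, left$col_max), c(159L, 180L))
  expect_identical(c(right$col_min, right$col_max), c(355L, 376L))
  expect_identical(c(left$row_min, left$row_max), c(132L, 372L))
  expect_identical(c(right$row_min, right$row_max), c(132L, 372L))
})

test_that("strips touching the image edge are valid; overflowing ones are not", {
  spec <- strip_spec(left_inner_offset = 10, right_inner_offset = 12,
                     strip_width = 4, extent_below_mid = 8, extent_above_mid = 8)
  # smallest image that still contains both strips
  rect <- strip_rectangles(17, 33, spec)
  expect_true(all(rect$col_min >= 0 & rect$col_max <= 32))
  expect_error(strip_rectangles(64, 64), "past the image edge")
})

test_that("binarization keeps pixels strictly below the threshold", {
  plane <- matrix(c(0L, 5L, 15L, 100L), 2, 2)
  expect_identical(binarize_plane(plane, 0), matrix(FALSE, 2, 2))
  expect_identical(binarize_plane(plane, 101), matrix(TRUE, 2, 2))
  expect_identical(binarize_plane(plane, 15), matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
})

test_that("zero periphery removal strips the border-connected zero component only", {
  plane <- matrix(50L, 20, 20)
  # circular FOV: zero corners touching the border
  plane[outer((1:20 - 10.5)^2, (1:20 - 10.5)^2, "+") > 9.5^2] <- 0L
  # an interior zero-valued pocket, disconnected from the corners
  plane[9:11, 9:11] <- 0L
  mask <- binarize_plane(plane, 20)
  out <- remove_zero_periphery(mask, plane)
  expect_false(any(out & plane == 0L & outer((1:20 - 10.5)^2, (1:20 - 10.5)^2, "+") > 9.5^2))
  expect_true(all(out[9:11, 9:11]))   # interior pocket survives as a region
})

test_that("planes without border zeros are unchanged; all-zero planes empty", {
  plane <- matrix(10L, 8, 8)
  mask <- binarize_plane(plane, 20)
  expect_identical(remove_zero_periphery(mask, plane), mask)
  z <- matrix(0L, 8, 8)
  expect_identical(sum(remove_zero_periphery(binarize_plane(z, 1), z)), 0L)
})

test_that("only regions intersecting a strip are kept", {
  spec <- strip_spec(5, 5, 3, 10, 10)
  rect <- strip_rectangles(40, 40, spec)
  mask <- matrix(FALSE, 40, 40)
  mask[18:22, 13:16] <- TRUE        # overlaps the left strip (cols 12..15)
  mask[2:4, 30:32] <- TRUE          # far outside both strips
  seg <- select_regions(mask, rect)
  expect_identical(nrow(seg$regions), 2L)
  expect_identical(sum(seg$regions$intersects_strip), 1L)
  expect_identical(sum(seg$mask), sum(mask[18:22, 13:16]))

  # one blob overlapping both strips is kept once
  wide <- matrix(FALSE, 40, 40)
  wide[19:21, 10:32] <- TRUE
  seg2 <- select_regions(wide, rect)
  expect_identical(nrow(seg2$regions), 1L)
  expect_identical(seg2$mask, wide)
})

test_that("an empty mask yields an empty segmentation", {
  rect <- strip_rectangles(40, 40, strip_spec(5, 5, 3, 10, 10))
  seg <- select_regions(matrix(FALSE, 40, 40), rect)
  expect_identical(nrow(seg$regions), 0L)
  expect_false(any(seg$mask))
})

test_that("2D labeling matches the flood-fill oracle on random masks", {
  set.seed(31)
  for (i in 1:400) {
    d <- sample(4:16, 2, TRUE)
    mask <- matrix(runif(prod(d)) < runif(1, 0.2, 0.7), d[1], d[2])
    got <- lungseg:::.label2d(mask)
    want <- label_oracle(mask)[, , 1]
    expect_identical(got, want)
  }
})

test_that("region selection is decided by membership, not label order", {
  spec <- strip_spec(5, 5, 3, 10, 10)
  rect <- strip_rectangles(40, 40, spec)
  set.seed(17)
  mask <- matrix(runif(1600) < 0.3, 40, 40)
  seg <- select_regions(mask, rect)
  strip <- lungseg:::.strip_mask(40, 40, rect)
  lab <- lungseg:::.label2d(mask)
  # brute-force: a pixel survives iff its component contains a strip pixel
  keep_labels <- unique(lab[strip & mask])
  keep_labels <- keep_labels[keep_labels > 0]
  expect_identical(seg$mask, matrix(lab %in% keep_labels, 40, 40))
  # every kept pixel belongs to a strip-intersecting region
  expect_true(all(lab[seg$mask] %in% keep_labels))
})
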