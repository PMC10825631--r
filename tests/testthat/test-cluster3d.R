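test_that("3D labeling uses 26-connectivity (diagonal plane contacts join)", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE     # touches only diagonally across planes
  cc <- connected_components_3d(m)
  expect_identical(nrow(cc$components), 1L)
  m[3, 3, 3] <- TRUE
  expect_identical(nrow(connected_components_3d(m)$components), 1L)
})

test_that("an empty stack has zero components", {
  cc <- connected_components_3d(array(FALSE, c(4, 4, 4)))
  expect_identical(nrow(cc$components), 0L)
})

test_that("components are sorted by size with voxel counts from the labels", {
  m <- array(FALSE, c(10, 10, 4))
  m[2:4, 2:4, 1] <- TRUE          # 9 voxels
  m[8:9, 8:9, 3:4] <- TRUE        # 8 voxels
  m[6, 1, 2] <- TRUE              # 1 voxel
  cc <- connected_components_3d(m)
  expect_identical(cc$components$voxel_count, c(9L, 8L, 1L))
  expect_identical(sum(cc$labels > 0), 18L)
})

test_that("3D labeling matches the flood-fill oracle on random stacks", {
  set.seed(57)
  for (i in 1:400) {
    d <- sample(3:12, 3, TRUE)
    mask <- array(runif(prod(d)) < runif(1, 0.15, 0.6), d)
    got <- connected_components_3d(mask)$labels
    want <- label_oracle(mask)
    expect_identical(got, want)
  }
})

test_that("mirror-flip test accepts a contralateral lung and rejects residuals", {
  d <- c(20, 30, 6)
  largest <- array(FALSE, d); second <- array(FALSE, d)
  # right lung: columns 19..26; its mirror is columns 5..12
  largest[5:15, 19:26, 2:5] <- TRUE
  second[5:15, 5:12, 2:5] <- TRUE
  res <- mirror_lobe_test(largest, second)
  expect_identical(res$n_lobes, 2L)
  expect_equal(res$overlap_fraction, 1)

  # residual blob near the border mirrors onto empty space
  resid <- array(FALSE, d)
  resid[1:2, 1:2, 1] <- TRUE
  res2 <- mirror_lobe_test(largest, resid)
  expect_identical(res2$n_lobes, 1L)
  expect_equal(res2$overlap_fraction, 0)

  # an empty second component means one lobe
  expect_identical(mirror_lobe_test(largest, array(FALSE, d))$n_lobes, 1L)
})

test_that("lung volume is exactly voxel count times voxel volume", {
  # 1e6 voxels at 0.7617 x 0.7617 x 2.2 mm
  geom <- list(in_plane_spacing = c(0.7617, 0.7617), plane_separation = 2.2)
  mask <- array(TRUE, c(100, 100, 100))
  rect <- strip_rectangles(100, 100, strip_spec(10, 10, 5, 20, 20))
  prof <- data.frame(plane = 1:100, raw_threshold = 10L, threshold = 10L,
                     rule = "right_min_below_tenth", exception = FALSE)
  cc <- connected_components_3d(mask)
  res <- assemble_result(cc, rect, prof, geom)
  expect_identical(res$n_lobes, 1L)
  expect_equal(res$lung_volume_L, 1e6 * 0.7617^2 * 2.2 / 1e6)
  expect_equal(res$lung_volume_L, sum(res$lung_mask) *
                 prod(geom$in_plane_spacing) * geom$plane_separation / 1e6)
})

test_that("segmentation failure is loud when nothing intersects the strips", {
  geom <- list(in_plane_spacing = c(1, 1), plane_separation = 1)
  rect <- strip_rectangles(40, 40, strip_spec(5, 5, 3, 10, 10))
  mask <- array(FALSE, c(40, 40, 3))
  mask[1:3, 1:3, 1] <- TRUE        # far from both strips
  prof <- data.frame(plane = 1:3, raw_threshold = 5L, threshold = 5L,
                     rule = "right_min_below_tenth", exception = FALSE)
  cc <- connected_components_3d(mask)
  expect_error(assemble_result(cc, rect, prof, geom),
               class = "lungseg_segmentation_failure")
})

test_that("strip-extruded filtering keeps only strip-intersecting components", {
  geom <- list(in_plane_spacing = c(1, 1), plane_separation = 1)
  spec <- strip_spec(5, 5, 3, 10, 10)
  rect <- strip_rectangles(40, 40, spec)
  mask <- array(FALSE, c(40, 40, 4))
  mask[15:25, 13:16, 2:3] <- TRUE   # in the left strip
  mask[1:3, 1:3, 1] <- TRUE         # residual far outside
  prof <- data.frame(plane = 1:4, raw_threshold = 5L, threshold = 5L,
                     rule = "right_min_below_tenth", exception = FALSE)
  res <- assemble_result(connected_components_3d(mask), rect, prof, geom)
  expect_identical(sum(res$components$intersects_strips), 1L)
  expect_identical(sum(res$components$kept), 1L)
  expect_identical(sum(res$lung_mask), sum(mask[15:25, 13:16, 2:3]))
})
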