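test_that("phantom generation is deterministic given the spec", {
  s <- small_phantom_spec(seed = 12)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$planes, b$volume$planes)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("noise-free voxelized lungs match the analytic ellipsoid volume", {
  s <- small_phantom_spec(noise = "none", psf_sigma_px = 0,
                          trachea_present = FALSE)
  ph <- generate_phantom(s)
  analytic <- 2 * (4 / 3) * pi * prod(s$lung_semiaxes_mm) / 1e6
  # voxelization error at a coarse raster stays within a surface layer
  expect_lt(abs(ph$true_volume_L - analytic) / analytic, 0.05)
})

test_that("ground truth excludes the airways but includes the lungs", {
  with_t <- generate_phantom(small_phantom_spec(seed = 5))
  no_t <- generate_phantom(small_phantom_spec(seed = 5, trachea_present = FALSE))
  expect_identical(with_t$ground_truth, no_t$ground_truth)
  # the trachea darkens voxels outside the truth
  dark_extra <- with_t$volume$planes < 200 & !with_t$ground_truth
  dark_extra_no <- no_t$volume$planes < 200 & !no_t$ground_truth
  expect_gt(sum(dark_extra), sum(dark_extra_no))
})

test_that("disconnected lungs form two components; a bridge joins them into one", {
  ph2 <- generate_phantom(small_phantom_spec())
  cc2 <- connected_components_3d(ph2$ground_truth)
  expect_identical(nrow(cc2$components), 2L)
  ph1 <- generate_phantom(small_phantom_spec(lung_connected = TRUE))
  cc1 <- connected_components_3d(ph1$ground_truth)
  expect_identical(nrow(cc1$components), 1L)
})

test_that("the normalized lung mode sits below the critical intensity of 12", {
  case <- small_case()
  norm <- normalize_volume(case$phantom$volume, preprocess_config())
  lung_vals <- norm$planes[case$phantom$ground_truth]
  mode_est <- as.integer(names(which.max(table(lung_vals))))
  expect_lt(mode_est, 12)
  # and tissue stays far above the search ceiling
  tissue <- norm$planes > 0 & !case$phantom$ground_truth
  expect_gt(median(norm$planes[tissue]), 32)
})

test_that("the raw intensity model spans the expected 16-bit working range", {
  case <- small_case()
  vals <- as.numeric(case$phantom$volume$planes)
  expect_gte(min(vals), 0)
  expect_gt(max(vals), 1200)   # tissue tail; fewer extreme draws at the coarse raster
  expect_lt(max(vals), 2500)
  # zero background outside the field of view
  corner <- case$phantom$volume$planes[1:3, 1:3, ]
  expect_true(all(corner == 0L))
})

test_that("lungs exceeding the field of view are rejected", {
  expect_error(small_phantom_spec(lung_semiaxes_mm = c(120, 105, 85)),
               "exceed the field of view")
})

test_that("cohort volume factors have the requested structure", {
  co <- generate_cohort(n_subjects = 4, sessions = 2, repeats = 2,
                        volume_cv = 0, subject_jitter = 0.1,
                        base_spec = small_phantom_spec(), seed = 2)
  expect_identical(nrow(co$table), 16L)
  # cv = 0: all acquisitions of a subject share the base size
  expect_true(all(tapply(co$table$volume_factor, co$table$subject,
                         function(x) length(unique(x))) == 1L))
  expect_true(all(abs(co$table$volume_factor - 1) <= 0.1))
  # per-case seeds are distinct and deterministic
  expect_identical(co$table$seed, (2L - 1L) * 16L + 1:16)
  co_b <- generate_cohort(4, 2, 2, volume_cv = 0, subject_jitter = 0.1,
                          base_spec = small_phantom_spec(), seed = 2)
  expect_identical(co$table, co_b$table)
})

test_that("a single-case cohort is a single case", {
  co <- generate_cohort(1, 1, 1, base_spec = small_phantom_spec(), seed = 1)
  expect_identical(nrow(co$table), 1L)
  expect_length(co$cases, 1L)
})

test_that("cohort true volumes recover the intrafractional CV through the metrics", {
  co <- generate_cohort(n_subjects = 21, sessions = 4, repeats = 2,
                        volume_cv = 0.03, subject_jitter = 0.10,
                        base_spec = small_phantom_spec(), seed = 7)
  tab <- co$table
  tab$volume_L <- tab$true_volume_L
  res <- intrafractional_deviations(tab)
  expect_lt(abs(res$sd - 0.03), 0.01)
})
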