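test_that("noise-free phantom has exact in-mask intensity and determinism", {
  ph <- quiet_phantom()
  st <- quiet_site(offset = 25)
  p1 <- make_phantom(ph, st, "responsive", seed = 3)
  p2 <- make_phantom(ph, st, "responsive", seed = 3)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$mask$data, p2$mask$data)
  inside <- p1$mask$data == 1
  expect_true(all(p1$image$data[inside] == 25 + 100))
  expect_true(all(p1$image$data[!inside] == 25))
  # single connected ellipsoid: voxel count matches the analytic volume
  expect_equal(sum(p1$mask$data), 4 / 3 * pi * 10^3, tolerance = 0.05)
})

test_that("phantom respects volume bounds and anisotropic spacing", {
  ph <- quiet_phantom(shape = c(16, 16, 16), axes = c(12, 12, 12))
  expect_error(make_phantom(ph, quiet_site(), "responsive", seed = 1),
               "exceeds volume")
  # anisotropic native grid still yields the right physical volume
  ph2 <- quiet_phantom(shape = c(64, 32, 32), axes = c(10, 10, 10))
  st2 <- quiet_site(spacing = c(0.5, 1, 1))
  p <- make_phantom(ph2, st2, "responsive", seed = 1)
  vox_vol <- prod(st2$voxel_spacing)
  expect_equal(sum(p$mask$data) * vox_vol, 4 / 3 * pi * 1000,
               tolerance = 0.05)
})

test_that("cohort counts, ids, and label balance follow the site specs", {
  sites <- list(site_spec("A", 10, responsive_fraction = 0.5, noise_sd = 1),
                site_spec("B", 5, responsive_fraction = 0.4, noise_sd = 1))
  ph <- phantom_spec(volume_shape = c(24, 24, 24),
                     tumor_axes_mean_responsive = c(4, 4, 4),
                     tumor_axes_mean_nonresponsive = c(6, 6, 6),
                     tumor_axes_sd = 0.5, texture_sd = 1)
  m <- generate_cohort(sites, ph, seed = 5, write = FALSE)
  expect_equal(nrow(m), 15L)
  expect_equal(sum(m$site_id == "A"), 10L)
  expect_false(anyDuplicated(m$patient_id) > 0)
  # exact-count mode: per-site responsive counts are deterministic
  expect_equal(sum(m$label == "responsive" & m$site_id == "A"), 5L)
  expect_equal(sum(m$label == "responsive" & m$site_id == "B"), 2L)
  expect_true(all(m$sex %in% c("M", "F")))

  # full determinism of the cohort in (specs, seed)
  m2 <- generate_cohort(sites, ph, seed = 5, write = FALSE)
  expect_identical(m$label, m2$label)
  expect_identical(attr(m, "axes"), attr(m2, "axes"))
})

test_that("cohort extension keeps earlier patients unchanged", {
  ph <- phantom_spec(volume_shape = c(24, 24, 24),
                     tumor_axes_mean_responsive = c(4, 4, 4),
                     tumor_axes_mean_nonresponsive = c(6, 6, 6),
                     tumor_axes_sd = 0.5, texture_sd = 1)
  s_small <- site_spec("A", 6, noise_sd = 1)
  s_big <- site_spec("A", 9, noise_sd = 1)
  m1 <- generate_cohort(list(s_small), ph, seed = 9, write = FALSE,
                        label_mode = "bernoulli")
  m2 <- generate_cohort(list(s_big), ph, seed = 9, write = FALSE,
                        label_mode = "bernoulli")
  expect_identical(m1$label, m2$label[seq_len(6)])
  v1 <- attr(m1, "volumes")
  v2 <- attr(m2, "volumes")
  for (pid in m1$patient_id) {
    expect_identical(v1[[pid]]$image$data, v2[[pid]]$image$data)
  }
})

test_that("NIfTI round trip preserves data and spacing", {
  dir <- withr::local_tempdir()
  sites <- list(site_spec("A", 2, noise_sd = 1,
                          voxel_spacing = c(1.25, 1.25, 2)))
  ph <- phantom_spec(volume_shape = c(20, 20, 16),
                     tumor_axes_mean_responsive = c(4, 4, 4),
                     tumor_axes_mean_nonresponsive = c(5, 5, 5),
                     tumor_axes_sd = 0.5, texture_sd = 1)
  m <- generate_cohort(sites, ph, seed = 2, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  v <- read_volume(m$image_path[1L])
  expect_equal(v$spacing, c(1.25, 1.25, 2))
  msk <- read_mask(m$mask_path[1L])
  expect_true(all(msk$data %in% c(0, 1)))
  expect_gt(sum(msk$data), 0)
})

test_that("morphological separability tracks label_effect_size", {
  ph_null <- phantom_spec(volume_shape = c(24, 24, 24),
                          tumor_axes_mean_responsive = c(4, 4, 4),
                          tumor_axes_mean_nonresponsive = c(8, 8, 8),
                          tumor_axes_sd = 1, texture_sd = 1,
                          label_effect_size = 0)
  site <- site_spec("A", 200, responsive_fraction = 0.5, noise_sd = 1)
  feature_auc <- function(effect) {
    ph <- ph_null
    ph$label_effect_size <- effect
    m <- generate_cohort(list(site), ph, seed = 31, write = FALSE)
    feat <- rowMeans(attr(m, "axes"))
    # nonresponsive tumors are larger: score on the nonresponsive class
    roc_auc(feat, as.integer(m$label == "nonresponsive"))
  }
  auc0 <- feature_auc(0)
  auc_half <- feature_auc(0.5)
  auc1 <- feature_auc(1)
  expect_lt(abs(auc0 - 0.5), 0.1)   # null: nothing to learn
  expect_gte(auc_half, auc0 - 0.02) # monotone in effect size
  expect_gte(auc1, auc_half - 0.02)
  expect_gte(auc1, 0.95)            # near-separable at full effect
})

test_that("bernoulli label mode stays within binomial bounds", {
  ph <- phantom_spec(volume_shape = c(20, 20, 20),
                     tumor_axes_mean_responsive = c(3, 3, 3),
                     tumor_axes_mean_nonresponsive = c(5, 5, 5),
                     tumor_axes_sd = 0.5, texture_sd = 1)
  site <- site_spec("A", 80, responsive_fraction = 0.45, noise_sd = 1)
  m <- generate_cohort(list(site), ph, seed = 13, write = FALSE,
                       label_mode = "bernoulli")
  k <- sum(m$label == "responsive")
  expect_lt(abs(k - 80 * 0.45), 3 * sqrt(80 * 0.45 * 0.55))
})
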