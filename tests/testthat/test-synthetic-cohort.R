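# The cohort generator: mask geometry, shrinkage, intensity synthesis,
# outcome calibration and determinism.

test_that("zero perturbation gives the exact voxelized ellipsoid", {
  cfg <- small_cohort_config(perturb_amplitude = 0, size_jitter = 0,
                             boundary_texture_range = c(0, 0), rng_seed = 2)
  m <- generate_parotid_mask(cfg, 1)
  # independent voxelization of the same ellipsoid
  dims <- cfg$grid_shape; sp <- cfg$spacing_mm; ax <- cfg$semiaxes_mm
  ctr <- (dims - 1) / 2
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1), k = 0:(dims[3] - 1))
  inside <- ((g$i - ctr[1]) * sp[1] / ax[1])^2 +
            ((g$j - ctr[2]) * sp[2] / ax[2])^2 +
            ((g$k - ctr[3]) * sp[3] / ax[3])^2 <= 1
  expect_equal(sum(m), sum(inside))
  expect_identical(as.vector(m), inside)
  # voxel count close to the analytic ellipsoid volume
  vol_analytic <- 4 / 3 * pi * prod(ax)
  expect_lt(abs(sum(m) * prod(sp) / vol_analytic - 1), 0.05)
})

test_that("mask generation is deterministic and well-formed", {
  cfg <- small_cohort_config(rng_seed = 7)
  m1 <- generate_parotid_mask(cfg, 3)
  m2 <- generate_parotid_mask(cfg, 3)
  expect_identical(as.vector(m1), as.vector(m2))
  for (i in 1:25) {
    m <- generate_parotid_mask(cfg, i)
    expect_equal(n_components(m, 6), 1)
    # strictly inside the grid
    expect_false(any(m[c(1, dim(m)[1]), , ]) || any(m[, c(1, dim(m)[2]), ]) ||
                 any(m[, , c(1, dim(m)[3])]))
  }
})

test_that("too-small grids fail with a sizing error naming the margin", {
  cfg <- small_cohort_config(rng_seed = 1)
  cfg$grid_shape <- c(12L, 12L, 6L)
  expect_error(generate_parotid_mask(cfg, 1), "grid too small.*mm")
})

test_that("shrinkage removes the requested volume fraction", {
  mk <- roi_mask(sphere_mask(10), spacing_mm = c(1, 1, 1))
  n0 <- sum(mk)
  half <- apply_weekly_shrinkage(mk, 0.5)
  expect_lt(abs(sum(half) / (0.5 * n0) - 1), 0.02)
  expect_true(all(which(half) %in% which(mk)))       # subset
  expect_equal(n_components(half, 6), 1)

  expect_identical(as.vector(apply_weekly_shrinkage(mk, 0)), as.vector(mk))
  expect_error(apply_weekly_shrinkage(mk, 1), "\\[0, 1\\)")
  expect_error(apply_weekly_shrinkage(mk, -0.1), "\\[0, 1\\)")
})

test_that("chained shrinkage yields a non-increasing nested volume sequence", {
  cfg <- small_cohort_config(rng_seed = 4)
  m <- generate_parotid_mask(cfg, 2)
  fr <- c(0.05, 0, 0.08, 0.02)
  vols <- sum(m)
  for (f in fr) {
    m2 <- apply_weekly_shrinkage(m, f)
    expect_true(all(which(m2) %in% which(m)))
    m <- m2
    vols <- c(vols, sum(m))
  }
  expect_true(all(diff(vols) <= 0))
})

test_that("intensity synthesis honours offsets, variance and the seed", {
  cfg <- small_cohort_config(rng_seed = 9)
  m <- generate_parotid_mask(cfg, 1)
  tp <- list(mean_hu = 45, sd_hu = 12, correlation_vox = 1.5, background_hu = -55)

  v0 <- synthesize_intensities(m, tp, contrast_offset_hu = 0, seed = 11)
  v80 <- synthesize_intensities(m, tp, contrast_offset_hu = 80, seed = 11)
  d <- as.numeric(v80[as_mask <- array(as.logical(m), dim(m))]) -
       as.numeric(v0[as_mask])
  expect_equal(d, rep(80, sum(m)))                       # exact voxelwise shift
  expect_equal(as.vector(v0[!as_mask]), as.vector(v80[!as_mask]))

  # zero texture variance -> constant ROI
  vc <- synthesize_intensities(m, utils::modifyList(tp, list(sd_hu = 0)), 0, 3)
  expect_equal(stats::sd(vc[as_mask]), 0)
  expect_equal(mean(vc[as_mask]), 45)

  # determinism and seed sensitivity
  expect_identical(as.vector(synthesize_intensities(m, tp, 0, 11)), as.vector(v0))
  expect_false(identical(as.vector(synthesize_intensities(m, tp, 0, 12)),
                         as.vector(v0)))

  # in-ROI sample mean is unbiased for the configured mean
  means <- vapply(1:30, function(s)
    mean(synthesize_intensities(m, tp, 0, s)[as_mask]), numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 45), 3 * se + 0.5)

  expect_error(synthesize_intensities(roi_mask(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("cohort truth is internally consistent and reproducible", {
  cfg <- small_cohort_config(n_patients = 6, rng_seed = 13)
  co1 <- generate_cohort(cfg, keep_images = FALSE)
  co2 <- generate_cohort(cfg, keep_images = FALSE)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$truth, co2$truth)

  # probability is exactly the inverse-logit of the linear predictor
  expect_equal(co1$truth$p_event, plogis(co1$truth$linear_predictor))

  # clinical/truth identical whether or not images are retained
  co3 <- generate_cohort(cfg, keep_images = TRUE)
  expect_identical(co1$clinical, co3$clinical)

  # with noise-free (hence non-negative) shrink fractions the weekly volumes
  # are non-increasing; the default allows mild transient growth (oedema)
  cfg0 <- small_cohort_config(n_patients = 3, rng_seed = 13, shrink_noise_sd = 0)
  co4 <- generate_cohort(cfg0, keep_images = TRUE)
  for (p in co4$patients) {
    v <- vapply(p$masks, sum, numeric(1))
    expect_true(all(diff(v) <= 0))
  }
})

test_that("a zero-coefficient outcome model gives 50% prevalence", {
  cfg <- cohort_config(outcome_betas = c(intercept = 0, xer_baseline = 0,
                                         dose_gy = 0, delta_surface_cm2 = 0),
                       rng_seed = 21)
  sim <- simulate_clinical_cohort(500, cfg)
  expect_equal(unique(sim$p_event), 0.5)
  ci <- stats::binom.test(sum(sim$xer_12m), 500, 0.5)$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})

test_that("event rate calibrates to the mean true probability at n = 2000", {
  sim <- simulate_clinical_cohort(2000, cohort_config(rng_seed = 31))
  p_bar <- mean(sim$p_event)
  se <- sqrt(p_bar * (1 - p_bar) / 2000)
  expect_lt(abs(mean(sim$xer_12m) - p_bar), 3 * se)
  expect_equal(sim$p_event, plogis(sim$linear_predictor))
})

test_that("noise-free shrinkage is perfectly rank-correlated with dose", {
  cfg <- cohort_config(shrink_noise_sd = 0, rng_seed = 5)
  sim <- simulate_clinical_cohort(100, cfg)
  # more dose -> larger fractional volume loss, with no noise term exactly
  expect_equal(unname(stats::cor(sim$dose_gy, 1 - sim$volume_ratio_w3,
                                 method = "spearman")), 1, tolerance = 1e-12)
})

test_that("cohort round-trips through NIfTI / CSV / JSON on disk", {
  cfg <- small_cohort_config(n_patients = 2, rng_seed = 17)
  co <- generate_cohort(cfg, keep_images = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  v <- read_volume(file.path(dir, "patient001_week0_ct.nii.gz"))
  expect_equal(dim(v), cfg$grid_shape)
  expect_equal(attr(v, "spacing"), cfg$spacing_mm, tolerance = 1e-6)
  expect_equal(as.vector(v), as.vector(co$patients[[1]]$volumes[[1]]),
               tolerance = 1e-6)
  m <- read_volume(file.path(dir, "patient002_week3_mask.nii.gz"))
  expect_equal(as.vector(m) > 0.5, as.vector(co$patients[[2]]$masks[[4]]))
})
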