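# Delta-feature construction: asymmetric baselines, sign convention,
# artefact-slice exclusion, proportional mode.

fv <- function(...) {
  v <- c(...)
  tibble::tibble(feature = names(v), value = unname(v))
}

test_that("geometric delta is later minus planning (shrinkage negative)", {
  f0 <- fv(surface_cm2 = 40, volume_cm3 = 30)
  fw <- fv(surface_cm2 = 37.27, volume_cm3 = 28)
  d <- geometric_delta(fw, f0)
  expect_equal(d$delta[d$feature == "surface_cm2"], -2.73)
  expect_equal(geometric_delta(f0, f0)$delta, c(0, 0))
  expect_error(geometric_delta(fv(surface_cm2 = 1), f0), "volume_cm3")
})

test_that("volume-times-mean delta equals recomputation from raw inputs", {
  v0 <- 30; m0 <- 50; v3 <- 27; m3 <- 48
  f0 <- fv(volume_x_mean_intensity = v0 * m0)
  f3 <- fv(volume_x_mean_intensity = v3 * m3)
  expect_equal(geometric_delta(f3, f0)$delta, v3 * m3 - v0 * m0)
})

test_that("texture deltas refuse the planning and week-1 scans", {
  f <- fv(median = 50)
  expect_equal(texture_delta(fv(median = 55), f, week = 3)$delta, 5)
  expect_equal(texture_delta(f, f, week = 2)$delta, 0)
  expect_error(texture_delta(f, f, week = 0), "weeks 2..6")
  expect_error(texture_delta(f, f, week = 1), "weeks 2..6")
})

test_that("proportional deltas are relative to the baseline magnitude", {
  expect_equal(proportional_delta(fv(x = 30), fv(x = 40))$delta, -0.25)
  expect_equal(proportional_delta(fv(x = 40), fv(x = 40))$delta, 0)
  # negative baseline: sign still follows the direction of change
  expect_equal(proportional_delta(fv(x = -30), fv(x = -40))$delta, 0.25)
  expect_warning(d <- proportional_delta(fv(x = 1), fv(x = 0)), "zero baseline")
  expect_true(is.na(d$delta))
})

test_that("absolute and proportional deltas agree in sign", {
  set.seed(8)
  for (rep in 1:20) {
    base <- rnorm(10); base[abs(base) < 0.05] <- 0.5
    wk <- base + rnorm(10)
    nm <- paste0("f", 1:10)
    fa <- fv(stats::setNames(wk, nm)); fb <- fv(stats::setNames(base, nm))
    da <- geometric_delta(fa, fb)$delta
    dp <- proportional_delta(fa, fb)$delta
    expect_true(all(sign(da) == sign(dp)))
  }
})

test_that("artefact-slice exclusion affects only the flagged slices", {
  cfg <- small_cohort_config(rng_seed = 3)
  m <- generate_parotid_mask(cfg, 1)
  v <- synthesize_intensities(m, contrast_offset_hu = 0, seed = 5)

  # no flags: identity
  r <- exclude_artifact_slices(v, m, integer(0))
  expect_identical(as.vector(r$mask), as.vector(m))

  # flags outside the mask's extent: unchanged features
  zs <- which(apply(m, 3, any))
  out_slices <- setdiff(seq_len(dim(m)[3]), zs)[1:2]
  r2 <- exclude_artifact_slices(v, m, out_slices)
  expect_identical(as.vector(r2$mask), as.vector(m))

  # flagging half the in-mask slices: mean over remaining voxels only
  half <- zs[seq_len(floor(length(zs) / 2))]
  r3 <- exclude_artifact_slices(v, m, half)
  ft <- extract_intensity(v, r3$mask)
  keep <- array(as.logical(m), dim(m)); keep[, , half] <- FALSE
  expect_equal(ft$value[ft$feature == "mean"], mean(v[keep]))

  expect_error(exclude_artifact_slices(v, m, zs), "empty")
})

test_that("a pure contrast offset moves intensity deltas but not texture", {
  cfg <- small_cohort_config(rng_seed = 6)
  m <- generate_parotid_mask(cfg, 1)
  v1 <- synthesize_intensities(m, contrast_offset_hu = 0, seed = 9)
  v2 <- synthesize_intensities(m, contrast_offset_hu = 80, seed = 9)
  f1 <- extract_features(v1, m)
  f2 <- extract_features(v2, m)
  d <- texture_delta(f2[, c("feature", "value")], f1[, c("feature", "value")],
                     week = 3)
  dv <- stats::setNames(d$delta, d$feature)
  expect_equal(unname(dv["median"]), 80)
  expect_equal(unname(dv["mean"]), 80)
  expect_equal(unname(dv["variance"]), 0, tolerance = 1e-9)
  # discretization is anchored at the ROI minimum, so all texture deltas vanish
  tex <- f1$feature[f1$family == "texture"]
  expect_equal(unname(dv[tex]), rep(0, length(tex)), tolerance = 1e-9)
  expect_equal(unname(dv["ngtdm_coarseness"]), 0, tolerance = 1e-9)
})

test_that("the cohort delta table enforces the asymmetric baselines", {
  # synthetic long feature table: 2 patients x weeks 0..6 x 2 features
  grid <- expand.grid(patient_id = 1:2, week = 0:6)
  features <- dplyr::bind_rows(
    dplyr::mutate(grid, feature = "surface_cm2", family = "geometric",
                  value = 50 - week - patient_id),
    dplyr::mutate(grid, feature = "median", family = "intensity",
                  value = 100 + 10 * week + patient_id))
  d <- delta_features(features)
  expect_setequal(unique(d$week), 2:6)

  geo <- dplyr::filter(d, feature == "surface_cm2", patient_id == 1)
  # baseline week 0: value(w) - value(0) = -w
  expect_equal(geo$delta[order(geo$week)], -(2:6))

  int <- dplyr::filter(d, feature == "median", patient_id == 1)
  # baseline week 1: 10 * (w - 1)
  expect_equal(int$delta[order(int$week)], 10 * (2:6 - 1))

  # a row exists only when both scans of the pair are present
  features_miss <- dplyr::filter(features, !(patient_id == 2 & week == 1))
  d2 <- delta_features(features_miss)
  expect_equal(nrow(dplyr::filter(d2, patient_id == 2, feature == "median")), 0)
  expect_equal(nrow(dplyr::filter(d2, patient_id == 2, feature == "surface_cm2")), 5)

  # proportional mode agrees in sign
  dp <- delta_features(features, mode = "proportional")
  j <- dplyr::inner_join(d, dp, by = c("patient_id", "week", "feature"))
  expect_true(all(sign(j$delta.x) == sign(j$delta.y)))
})

test_that("monotone shrinkage makes per-patient surface deltas non-increasing", {
  # build an explicitly monotone weekly series (all shrink fractions >= 0)
  cfg <- small_cohort_config(rng_seed = 19)
  m <- generate_parotid_mask(cfg, 1)
  fr <- c(0.03, 0.02, 0.05, 0, 0.04, 0.03)
  masks <- list(m)
  for (w in 1:6) masks[[w + 1]] <- apply_weekly_shrinkage(masks[[w]], fr[w])
  surf <- vapply(masks, function(mm)
    xerodelta:::mesh_surface_area_mm2(array(as.logical(mm), dim(mm)),
                                      cfg$spacing_mm) / 100, numeric(1))
  deltas <- surf[-1] - surf[1]       # weekly surface change vs planning
  expect_true(all(diff(deltas) <= 1e-6))
  expect_true(all(deltas <= 1e-6))
})
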