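# Geometric, intensity and texture feature extraction against independent
# oracles: analytic solids, hand arithmetic, and brute-force matrix
# enumeration on tiny ROIs.

test_that("sphere geometry matches the analytic ball", {
  r <- 12
  mk <- roi_mask(sphere_mask(r), spacing_mm = c(1, 1, 1))
  ft <- extract_geometric(mk)
  val <- function(f) ft$value[ft$feature == f]
  expect_lt(abs(val("surface_cm2") * 100 / (4 * pi * r^2) - 1), 0.02)
  expect_lt(abs(val("volume_cm3") * 1000 / (4 / 3 * pi * r^3) - 1), 0.02)
  expect_lt(abs(val("sphericity") - 1), 0.03)
  # diameter of a ball = 2r (voxel-centre measure within one voxel)
  expect_lt(abs(val("max_diameter_mm") - 2 * r), 1.5)
})

test_that("cube volume and bounding box are exact", {
  cb <- array(FALSE, c(14, 14, 14)); cb[3:12, 3:12, 3:12] <- TRUE
  ft <- extract_geometric(roi_mask(cb, c(1, 1, 1)))
  expect_equal(ft$value[ft$feature == "volume_cm3"], 1)          # 1000 mm^3
  expect_equal(ft$value[ft$feature == "bbox_volume_cm3"], 1)
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  f1 <- extract_geometric(roi_mask(sv, c(1, 1, 1)))
  expect_equal(f1$value[f1$feature == "bbox_volume_cm3"], 0.001)
  expect_true(all(is.finite(f1$value)))                          # degenerate ROI stays finite
})

test_that("anisotropic spacing scales volumes correctly", {
  cb <- array(FALSE, c(12, 12, 8)); cb[3:10, 3:10, 3:6] <- TRUE
  ft <- extract_geometric(roi_mask(cb, c(0.94, 0.94, 2)))
  expect_equal(ft$value[ft$feature == "volume_cm3"],
               8 * 8 * 4 * 0.94 * 0.94 * 2 / 1000)
})

test_that("empty and multi-component masks are handled per contract", {
  expect_error(extract_geometric(roi_mask(array(FALSE, c(4, 4, 4)))), "empty")
  two <- array(FALSE, c(9, 5, 5)); two[2, 2, 2] <- TRUE; two[8, 4, 4] <- TRUE
  expect_warning(extract_geometric(roi_mask(two, c(1, 1, 1))), "component")
})

test_that("first-order intensity features match hand arithmetic", {
  m <- array(FALSE, c(5, 5, 1)); m[1:5, 1, 1] <- TRUE
  v <- array(0, c(5, 5, 1)); v[1:5, 1, 1] <- c(1, 2, 3, 4, 100)
  ft <- extract_intensity(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)))
  val <- function(f) ft$value[ft$feature == f]
  expect_equal(val("median"), 3)
  expect_equal(val("mean"), 22)
  expect_equal(val("min"), 1)
  expect_equal(val("max"), 100)
  expect_equal(val("energy"), sum(c(1, 2, 3, 4, 100)^2))

  # constant ROI: degenerate but defined
  v[m] <- 7
  ftc <- extract_intensity(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)))
  valc <- function(f) ftc$value[ftc$feature == f]
  expect_equal(valc("mean"), 7)
  expect_equal(valc("median"), 7)
  expect_equal(valc("variance"), 0)
  expect_equal(valc("entropy"), 0)
  expect_true(all(is.finite(ftc$value)))
})

test_that("kurtosis uses the Pearson (non-excess) convention", {
  set.seed(11)
  n <- 1e5
  m <- array(TRUE, c(50, 50, 40))
  v <- array(rnorm(prod(dim(m))), dim(m))
  ft <- extract_intensity(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)))
  expect_lt(abs(ft$value[ft$feature == "kurtosis"] - 3), 0.1)
  expect_lt(abs(ft$value[ft$feature == "skewness"]), 0.05)
})

test_that("discretization follows the fixed-bin-width formula", {
  m <- array(FALSE, c(4, 1, 1)); m[1:4, 1, 1] <- TRUE
  v <- array(0, c(4, 1, 1)); v[1:4, 1, 1] <- c(0, 24.9, 25, 50)
  d <- discretize(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)), 25)
  expect_equal(d$levels[m], c(1L, 1L, 2L, 3L))
  expect_equal(d$n_levels, 3L)

  # translation invariance
  d2 <- discretize(volume_grid(v + 100, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)), 25)
  expect_identical(d$levels, d2$levels)

  # constant ROI collapses to a single level
  v[m] <- 42
  d3 <- discretize(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)), 25)
  expect_equal(unique(d3$levels[m]), 1L)
  expect_equal(d3$n_levels, 1L)

  expect_error(discretize(volume_grid(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)), 0),
               "positive")
})

test_that("GLCM features match the exhaustive pair-enumeration oracle", {
  for (seed in 1:3) {
    lev <- random_levels(c(5, 5, 4), ng = 3, seed = seed)
    droi <- make_droi(lev)
    P <- xerodelta:::cpp_glcm(as.vector(lev), dim(lev), 3)
    expect_equal(P, oracle_glcm(lev, 3), tolerance = 1e-12)
    expect_equal(sum(P), 1, tolerance = 1e-12)   # normalised
  }
})

test_that("checkerboard GLCM has contrast 1 in an in-plane direction", {
  # 2D checkerboard of levels 1/2: every distance-1 in-plane co-occurrence is
  # a (1,2) or (2,1) pair, so the single-direction contrast is exactly 1
  n <- 6
  lev <- array(0L, c(n, n, 1))
  for (i in 1:n) for (j in 1:n) lev[i, j, 1] <- 1L + (i + j) %% 2L
  M <- oracle_glcm(lev, 2, dirs = matrix(c(1, 0, 0), 1))
  ij <- expand.grid(i = 1:2, j = 1:2)
  expect_equal(sum((ij$i - ij$j)^2 * M[cbind(ij$i, ij$j)]), 1)
  # and the 13-direction implementation agrees with the 13-direction oracle
  expect_equal(xerodelta:::cpp_glcm(as.vector(lev), dim(lev), 2),
               oracle_glcm(lev, 2), tolerance = 1e-12)
})

test_that("constant ROI gives degenerate but defined GLCM values", {
  lev <- array(1L, c(4, 4, 3))
  ft <- glcm_features(make_droi(lev))
  val <- function(f) ft$value[ft$feature == f]
  expect_equal(val("glcm_contrast"), 0)
  expect_equal(val("glcm_energy"), 1)
  expect_equal(val("glcm_correlation"), 0)   # zero-variance convention
  expect_true(all(is.finite(ft$value)))
})

test_that("GLCM contrast and energy are invariant under level reversal", {
  for (seed in 4:6) {
    lev <- random_levels(c(5, 5, 5), ng = 4, seed = seed)
    rev <- lev
    rev[lev > 0] <- 5L - lev[lev > 0]
    f1 <- glcm_features(make_droi(lev))
    f2 <- glcm_features(make_droi(rev))
    for (f in c("glcm_contrast", "glcm_energy", "glcm_joint_entropy")) {
      expect_equal(f1$value[f1$feature == f], f2$value[f2$feature == f],
                   tolerance = 1e-12)
    }
  }
})

test_that("GLRLM matches the exhaustive run-enumeration oracle", {
  for (seed in 1:3) {
    lev <- random_levels(c(4, 4, 4), ng = 3, seed = seed)
    R <- xerodelta:::cpp_glrlm(as.vector(lev), dim(lev), 3)
    O <- oracle_glrlm(lev, 3)
    expect_equal(R[, seq_len(ncol(O))], O, tolerance = 1e-12)
    expect_true(all(R[, -seq_len(ncol(O))] == 0))
  }
})

test_that("run-length features behave as forced by their definitions", {
  # straight constant segment: along its axis a single run of length L
  L <- 6
  lev <- array(0L, c(L, 3, 3)); lev[1:L, 2, 2] <- 1L
  O1 <- oracle_glrlm(lev, 1, dirs = matrix(c(1, 0, 0), 1))
  expect_equal(O1[1, L], 1)             # one run of length L
  expect_equal(sum(O1), 1)
  # LRE of that single-direction matrix is L^2
  expect_equal(sum(O1 %*% diag(seq_len(ncol(O1))^2)) / sum(O1), L^2)

  # strictly alternating levels: all runs have length 1, run percentage 1
  lev2 <- array(0L, c(8, 1, 1)); lev2[1:8, 1, 1] <- rep(c(1L, 2L), 4)
  ft <- glrlm_features(make_droi(lev2))
  expect_equal(ft$value[ft$feature == "glrlm_rp"], 1)
  expect_equal(ft$value[ft$feature == "glrlm_sre"], 1)
})

test_that("GLSZM matches the connected-component oracle", {
  for (seed in 1:3) {
    lev <- random_levels(c(4, 4, 4), ng = 3, seed = seed)
    Z <- xerodelta:::cpp_glszm(as.vector(lev), dim(lev), 3)
    O <- oracle_glszm(lev, 3)
    expect_equal(Z[, seq_len(ncol(O))], O, tolerance = 1e-12)
  }

  # constant ROI of V voxels: one zone, LZE = V^2
  lev <- array(1L, c(3, 3, 3))
  ft <- glszm_features(make_droi(lev))
  expect_equal(ft$value[ft$feature == "glszm_lze"], 27^2)
  expect_equal(ft$value[ft$feature == "glszm_zone_percentage"], 1 / 27)

  # two disjoint level-1 voxels in a level-2 sea
  sea <- array(2L, c(5, 5, 3))
  sea[1, 1, 1] <- 1L; sea[5, 5, 3] <- 1L
  Z <- xerodelta:::cpp_glszm(as.vector(sea), dim(sea), 2)
  expect_equal(Z[1, 1], 2)                       # two singleton level-1 zones
  expect_equal(Z[2, 5 * 5 * 3 - 2], 1)           # one big level-2 zone
  expect_equal(sum(Z), 3)
})

test_that("LZLGE rises when a large zone's grey level is lowered", {
  big <- array(3L, c(4, 4, 2))     # one large level-3 zone
  big[1, 1, 1] <- 1L               # plus a singleton to keep ng fixed
  lower <- big
  lower[big == 3L] <- 2L           # same zones, lower level for the large one
  f_hi <- glszm_features(make_droi(big))
  f_lo <- glszm_features(make_droi(lower))
  expect_gt(f_lo$value[f_lo$feature == "glszm_lzlge"],
            f_hi$value[f_hi$feature == "glszm_lzlge"])
})

test_that("NGTDM matches the neighbourhood oracle and conventions", {
  for (seed in 1:3) {
    lev <- random_levels(c(4, 4, 4), ng = 3, seed = seed)
    M <- xerodelta:::cpp_ngtdm(as.vector(lev), dim(lev), 3)
    expect_equal(unname(M), unname(oracle_ngtdm(lev, 3)), tolerance = 1e-12)
  }

  # single interior voxel of level 2 in a level-1 sea: s_2 = |2 - 1| = 1
  sea <- array(1L, c(5, 5, 5)); sea[3, 3, 3] <- 2L
  M <- xerodelta:::cpp_ngtdm(as.vector(sea), dim(sea), 2)
  expect_equal(M[2, 1], 1)
  expect_equal(M[2, 2], 1)
  expect_equal(unname(M), unname(oracle_ngtdm(sea, 2)), tolerance = 1e-12)

  # constant ROI: coarseness capped at 1/eps, contrast 0
  ft <- ngtdm_features(make_droi(array(1L, c(4, 4, 4))))
  expect_equal(ft$value[ft$feature == "ngtdm_coarseness"], 1e6)
  expect_equal(ft$value[ft$feature == "ngtdm_contrast"], 0)
})

test_that("coarseness drops when high-frequency noise is added", {
  smooth <- array(2L, c(6, 6, 6))
  set.seed(3)
  noisy <- smooth
  flip <- sample(length(noisy), 80)
  noisy[flip] <- sample(c(1L, 3L), 80, replace = TRUE)
  c_smooth <- ngtdm_features(make_droi(smooth))
  c_noisy <- ngtdm_features(make_droi(noisy))
  expect_gt(c_smooth$value[c_smooth$feature == "ngtdm_coarseness"],
            c_noisy$value[c_noisy$feature == "ngtdm_coarseness"])
})

test_that("full extraction returns the complete finite catalogue", {
  cfg <- small_cohort_config(rng_seed = 5)
  p <- xerodelta:::generate_patient(cfg, 1)
  ft <- extract_features(p$volumes[[1]], p$masks[[1]])
  cat_all <- unlist(feature_catalogue(), use.names = FALSE)
  expect_setequal(ft$feature, cat_all)
  expect_true(all(is.finite(ft$value)))
  # texture is computed on the lattice: rescaling spacing leaves texture
  # untouched but scales volumes
  m2 <- roi_mask(array(as.logical(p$masks[[1]]), dim(p$masks[[1]])),
                 spacing_mm = c(2, 2, 4))
  v2 <- volume_grid(array(as.numeric(p$volumes[[1]]), dim(p$volumes[[1]])),
                    c(2, 2, 4))
  ft2 <- extract_features(v2, m2)
  tex <- ft$family == "texture"
  expect_equal(ft2$value[tex], ft$value[tex], tolerance = 1e-10)
  expect_equal(ft2$value[ft2$feature == "volume_cm3"],
               8 * ft$value[ft$feature == "volume_cm3"], tolerance = 1e-10)
})
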