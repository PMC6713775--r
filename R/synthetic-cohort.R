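#' Configuration of the synthetic longitudinal cohort generator
#'
#' Defines the study conditions the generator emulates: a head-and-neck
#' radiotherapy cohort with a planning CT (week 0, intravenous contrast) and
#' six weekly CTs of a contralateral parotid-like ROI that shrinks week by
#' week at a dose-correlated but noisy rate, CT-like in-ROI texture, and a
#' late-xerostomia outcome drawn from a known logistic truth on baseline
#' xerostomia, mean gland dose (Gy) and the true week-3 surface change (cm^2).
#'
#' Default outcome coefficients are the uncorrected delta-feature "model 2"
#' truth: intercept -4.515, baseline xerostomia 2.591, dose 0.072 per Gy,
#' surface change -0.481 per cm^2. Default voxel spacing is
#' 0.94 x 0.94 x 2.0 mm.
#'
#' @param n_patients cohort size (>= 2); default 68.
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param spacing_mm voxel spacing in mm.
#' @param dose_mean_gy,dose_sd_gy mean contralateral parotid dose distribution.
#' @param shrink_dose_slope fractional ROI volume loss per Gy per week.
#' @param shrink_noise_sd SD of the weekly fractional-shrinkage noise.
#' @param shape_noise_sd SD of the weekly anisotropic-erosion strength
#'   (directional flattening on top of the uniform shrinkage).
#' @param boundary_texture_range per-patient range (uniform) of the relative
#'   amplitude of the fine-scale random boundary texture of the baseline
#'   gland. Erosion removes surface irregularity preferentially, so glands
#'   with a rough baseline boundary lose much more surface per unit volume
#'   than smooth ones. This morphological heterogeneity keeps the
#'   surface-volume delta correlation at the realistic 0.8-0.9 level instead
#'   of the ~1 that purely radial erosion of one smooth template gives.
#' @param baseline_xer_prevalence probability of baseline xerostomia.
#' @param outcome_betas named vector `intercept`, `xer_baseline`, `dose_gy`,
#'   `delta_surface_cm2` for the 12-month outcome.
#' @param acute_betas named vector `intercept`, `xer_baseline`, `dose_gy` for
#'   the weekly (acute) xerostomia link.
#' @param xer_6m_shift additive shift of the 12-month linear predictor used
#'   for the higher-prevalence 6-month endpoint.
#' @param contrast_offset_hu HU offset applied to the planning scan only
#'   (intravenous contrast).
#' @param texture_params list: `mean_hu`, `sd_hu`, `correlation_vox`,
#'   `background_hu`.
#' @param semiaxes_mm ellipsoid template semi-axes (mm).
#' @param size_jitter multiplicative half-range of the per-patient linear
#'   size factor (uniform on `1 +/- size_jitter`).
#' @param perturb_amplitude relative amplitude of the low-frequency random
#'   boundary perturbation (0 gives an exact voxelized ellipsoid).
#' @param rng_seed integer master seed; all per-patient randomness is derived
#'   from it, so identical config + seed reproduces the cohort exactly.
#' @return object of class `cohort_config` (a validated list)
#' @export
cohort_config <- function(n_patients = 68,
                          grid_shape = c(64L, 48L, 44L),
                          spacing_mm = c(0.94, 0.94, 2.0),
                          dose_mean_gy = 20,
                          dose_sd_gy = 12,
                          shrink_dose_slope = 0.001,
                          shrink_noise_sd = 0.033,
                          shape_noise_sd = 0.5,
                          boundary_texture_range = c(0.02, 0.10),
                          baseline_xer_prevalence = 0.38,
                          outcome_betas = c(intercept = -4.515,
                                            xer_baseline = 2.591,
                                            dose_gy = 0.072,
                                            delta_surface_cm2 = -0.481),
                          acute_betas = c(intercept = -2.6,
                                          xer_baseline = 1.0,
                                          dose_gy = 0.04),
                          xer_6m_shift = 0.55,
                          contrast_offset_hu = 80,
                          texture_params = list(mean_hu = 45, sd_hu = 12,
                                                correlation_vox = 1.5,
                                                background_hu = -55),
                          semiaxes_mm = c(20, 14, 28),
                          size_jitter = 0.08,
                          perturb_amplitude = 0.10,
                          rng_seed = 1L) {
  stopifnot(n_patients >= 2, length(grid_shape) == 3, all(grid_shape > 0),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            dose_sd_gy >= 0, shrink_noise_sd >= 0,
            baseline_xer_prevalence >= 0, baseline_xer_prevalence <= 1,
            perturb_amplitude >= 0, size_jitter >= 0, size_jitter < 1)
  need <- c("intercept", "xer_baseline", "dose_gy", "delta_surface_cm2")
  if (!all(need %in% names(outcome_betas)))
    stop("`outcome_betas` must name: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm), dose_mean_gy = dose_mean_gy,
    dose_sd_gy = dose_sd_gy, shrink_dose_slope = shrink_dose_slope,
    shrink_noise_sd = shrink_noise_sd, shape_noise_sd = shape_noise_sd,
    boundary_texture_range = boundary_texture_range,
    baseline_xer_prevalence = baseline_xer_prevalence,
    outcome_betas = outcome_betas, acute_betas = acute_betas,
    xer_6m_shift = xer_6m_shift, contrast_offset_hu = contrast_offset_hu,
    texture_params = texture_params, semiaxes_mm = as.numeric(semiaxes_mm),
    size_jitter = size_jitter, perturb_amplitude = perturb_amplitude,
    rng_seed = as.integer(rng_seed)), class = "cohort_config")
}

#' Generate one parotid-like ROI mask
#'
#' Voxelizes an ellipsoid template (per-patient size jitter) whose boundary is
#' modulated by a smooth low-order random angular perturbation, centred in the
#' grid. With `perturb_amplitude = 0` the result is the exact voxelized
#' ellipsoid.
#'
#' @param config [cohort_config()]
#' @param patient_index positive integer; drives the per-patient random draw.
#' @return an [roi_mask()]
#' @export
generate_parotid_mask <- function(config, patient_index = 1L) {
  sp <- config$spacing_mm
  dims <- config$grid_shape
  with_seed(child_seed(config$rng_seed, 101, patient_index), {
    scale <- 1 + runif(1, -config$size_jitter, config$size_jitter)
    ax <- config$semiaxes_mm * scale
    # low-frequency angular modulation: quadratic + linear forms in direction
    U <- matrix(rnorm(12), 4, 3); U <- U / sqrt(rowSums(U^2))
    cu <- rnorm(4)
    V <- matrix(rnorm(9), 3, 3); V <- V / sqrt(rowSums(V^2))
    dv <- rnorm(3)
    A <- config$perturb_amplitude

    extent_mm <- ax * (1 + A + 2 * max(config$boundary_texture_range %||% 0)) +
      sp                                    # one-voxel margin
    half_mm <- (dims - 1) * sp / 2
    if (any(extent_mm > half_mm))
      stop(sprintf(
        "grid too small for ROI: need half-extents >= (%.1f, %.1f, %.1f) mm but grid offers (%.1f, %.1f, %.1f) mm",
        extent_mm[1], extent_mm[2], extent_mm[3],
        half_mm[1], half_mm[2], half_mm[3]), call. = FALSE)

    ctr <- (dims - 1) / 2
    gx <- ((seq_len(dims[1]) - 1) - ctr[1]) * sp[1]
    gy <- ((seq_len(dims[2]) - 1) - ctr[2]) * sp[2]
    gz <- ((seq_len(dims[3]) - 1) - ctr[3]) * sp[3]
    X <- array(gx, dims)
    Y <- array(rep(gy, each = dims[1]), dims)
    Z <- array(rep(gz, each = dims[1] * dims[2]), dims)
    r <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
    bump <- 0
    rng_a2 <- config$boundary_texture_range %||% c(0, 0)
    A2 <- runif(1, rng_a2[1], rng_a2[2])
    if (A2 > 0) {
      # fine-scale boundary texture: correlated noise on the radial coordinate
      eta <- array(rnorm(prod(dims)), dims)
      eta <- array(cpp_gauss3(as.vector(eta), dims, rep(2.5, 3)), dims)
      bump <- A2 * pmin(pmax(eta / stats::sd(eta), -2), 2)   # bounded excursion
    }
    m <- r <= 1 + bump
    if (A > 0) {
      rr <- sqrt(X^2 + Y^2 + Z^2); rr[rr == 0] <- 1
      nx <- X / rr; ny <- Y / rr; nz <- Z / rr
      f <- dv[1] * (nx * V[1, 1] + ny * V[1, 2] + nz * V[1, 3]) +
           dv[2] * (nx * V[2, 1] + ny * V[2, 2] + nz * V[2, 3]) +
           dv[3] * (nx * V[3, 1] + ny * V[3, 2] + nz * V[3, 3])
      for (q in 1:4) {
        proj <- nx * U[q, 1] + ny * U[q, 2] + nz * U[q, 3]
        f <- f + cu[q] * (proj^2 - 1 / 3)
      }
      f <- f / max(abs(f))
      m <- r <= 1 + A * f + bump
    }
    # keep the largest 6-connected component (fine texture can pinch off
    # isolated crumbs at the boundary)
    lab <- cpp_label(as.vector(m), dims, 6L)
    if (max(lab) > 1) {
      main <- which.max(tabulate(lab[lab > 0]))
      m <- array(lab == main, dims)
    }
    mask <- roi_mask(m, spacing_mm = sp)
    if (n_components(mask, 6) != 1)
      stop("generated mask is not a single 6-connected component; ",
           "reduce `perturb_amplitude`", call. = FALSE)
    mask
  })
}

#' Shrink a ROI by a volume fraction while keeping it compact
#'
#' Removes the requested fraction of voxels from the outside in, by ranking
#' voxels on the Gaussian-smoothed internal Euclidean distance transform and
#' keeping the deepest ones. This smooth erosion preserves the single-component
#' topology that morphological erosion can break.
#'
#' With `shape_bias` the erosion is directional: voxels on the
#' `direction`-facing side lose ranking depth, so the gland flattens while the
#' removed volume fraction stays exactly as requested. This decouples surface
#' change from volume change the way real irradiated glands do.
#'
#' @param mask [roi_mask()]
#' @param shrink_fraction fraction of the ROI volume to remove, in `[0, 1)`.
#' @param shape_bias optional list with unit `direction` (length-3) and scalar
#'   `strength`; positive strength erodes preferentially from that side.
#' @param smooth_sigma_vox Gaussian scale (voxels) applied to the distance
#'   transform before thresholding. Larger values erode surface irregularity
#'   preferentially, giving a stronger surface drop per unit volume loss.
#' @return an [roi_mask()], always a subset of the input mask, with voxel
#'   count `round((1 - shrink_fraction) * n)`.
#' @export
apply_weekly_shrinkage <- function(mask, shrink_fraction, shape_bias = NULL,
                                   smooth_sigma_vox = 1) {
  if (!is.numeric(shrink_fraction) || length(shrink_fraction) != 1 ||
      is.na(shrink_fraction) || shrink_fraction < 0 || shrink_fraction >= 1)
    stop("`shrink_fraction` must be a single value in [0, 1)", call. = FALSE)
  m <- as_mask_array(mask)
  if (shrink_fraction == 0) return(roi_mask(m, spacing_of(mask),
                                            attr(mask, "artifact_slices") %||% integer(0)))
  sp <- spacing_of(mask)
  d <- cpp_distance_inside(as.vector(m), dim(m), sp)
  ds <- cpp_gauss3(d, dim(m), rep(smooth_sigma_vox, 3))
  inside <- which(m)
  if (!is.null(shape_bias)) {
    idx <- which(m, arr.ind = TRUE)
    coords <- sweep(idx - 1, 2, sp, "*")
    u <- shape_bias$direction / sqrt(sum(shape_bias$direction^2))
    proj <- as.vector(coords %*% u)
    proj <- (proj - mean(proj)) / max(abs(proj - mean(proj)))   # in [-1, 1]
    ds[inside] <- ds[inside] * (1 - shape_bias$strength * proj)
  }
  keep_n <- round((1 - shrink_fraction) * length(inside))
  ord <- inside[order(ds[inside], decreasing = TRUE)]   # ties: voxel order
  out <- array(FALSE, dim(m))
  out[ord[seq_len(keep_n)]] <- TRUE
  roi_mask(out, sp, attr(mask, "artifact_slices") %||% integer(0))
}

# weekly resize used by the generator: shrink (delegated to
# apply_weekly_shrinkage) or mild transient growth (edema) by ranking
# background voxels on the smoothed signed distance field
resize_mask <- function(mask, fraction, shape_bias = NULL) {
  if (fraction >= 0) return(apply_weekly_shrinkage(mask, fraction, shape_bias))
  m <- as_mask_array(mask)
  sp <- spacing_of(mask)
  sdf <- cpp_gauss3(cpp_signed_edt(as.vector(m), dim(m), sp), dim(m), rep(1, 3))
  outside <- which(!m)
  add_n <- round(-fraction * sum(m))
  ord <- outside[order(sdf[outside], decreasing = TRUE)]
  add_n <- min(add_n, length(ord))
  m[ord[seq_len(add_n)]] <- TRUE
  roi_mask(m, sp, attr(mask, "artifact_slices") %||% integer(0))
}

#' Synthesize CT-like intensities for a ROI
#'
#' In-ROI intensities are `mean_hu + contrast_offset_hu` plus a correlated
#' Gaussian field (white noise smoothed to the configured correlation length,
#' rescaled to `sd_hu`). The background is a distinct `background_hu` level
#' carrying the same texture field. Deterministic for a given seed: changing
#' only `contrast_offset_hu` shifts in-ROI voxels by exactly that amount.
#'
#' @param mask [roi_mask()] (non-empty)
#' @param texture_params list with `mean_hu`, `sd_hu`, `correlation_vox`,
#'   `background_hu`
#' @param contrast_offset_hu additive in-ROI offset (HU)
#' @param seed integer seed
#' @return a [volume_grid()]
#' @export
synthesize_intensities <- function(mask,
                                   texture_params = list(mean_hu = 45, sd_hu = 12,
                                                         correlation_vox = 1.5,
                                                         background_hu = -55),
                                   contrast_offset_hu = 0, seed = 1L) {
  m <- as_mask_array(mask)
  if (!any(m)) stop("cannot synthesize intensities for an empty mask", call. = FALSE)
  tp <- utils::modifyList(list(mean_hu = 45, sd_hu = 12, correlation_vox = 1.5,
                               background_hu = -55), as.list(texture_params))
  dims <- dim(m)
  field <- with_seed(seed, array(rnorm(prod(dims)), dims))
  if (tp$correlation_vox > 0) {
    field <- cpp_gauss3(as.vector(field), dims, rep(tp$correlation_vox, 3))
    field <- array(field, dims)
    s <- stats::sd(field)
    if (s > 0) field <- field / s
  }
  vol <- array(tp$background_hu + tp$sd_hu * field, dims)
  vol[m] <- tp$mean_hu + contrast_offset_hu + tp$sd_hu * field[m]
  volume_grid(vol, spacing_of(mask))
}

# All latent draws and scans for a single patient. Weekly scans are modelled
# as acquired after that week's irradiation, so the week-w mask has undergone
# w shrink steps.
generate_patient <- function(config, i, keep_images = TRUE) {
  sd0 <- child_seed(config$rng_seed, 202, i)
  lat <- with_seed(sd0, {
    dose <- min(max(rnorm(1, config$dose_mean_gy, config$dose_sd_gy), 1), 75)
    dirs <- matrix(rnorm(18), 6, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    list(dose = dose,
         xer_baseline = rbinom(1, 1, config$baseline_xer_prevalence),
         shrink = pmax(-0.05, rnorm(6, config$shrink_dose_slope * dose,
                                    config$shrink_noise_sd)),
         shape_dir = dirs,
         shape_strength = pmin(pmax(rnorm(6, 0, config$shape_noise_sd %||% 0),
                                    -0.9), 0.9))
  })
  mask0 <- generate_parotid_mask(config, i)
  masks <- vector("list", 7)
  masks[[1]] <- mask0
  for (w in 1:6)
    masks[[w + 1]] <- resize_mask(
      masks[[w]], lat$shrink[w],
      shape_bias = if ((config$shape_noise_sd %||% 0) > 0)
        list(direction = lat$shape_dir[w, ],
             strength = lat$shape_strength[w]))
  sp <- config$spacing_mm
  s0 <- mesh_surface_area_mm2(as_mask_array(mask0), sp) / 100
  s3 <- mesh_surface_area_mm2(as_mask_array(masks[[4]]), sp) / 100
  dsurf3 <- s3 - s0

  b <- config$outcome_betas
  lp <- unname(b["intercept"] + b["xer_baseline"] * lat$xer_baseline +
               b["dose_gy"] * lat$dose + b["delta_surface_cm2"] * dsurf3)
  a <- config$acute_betas
  out <- with_seed(child_seed(config$rng_seed, 303, i), {
    p12 <- plogis(lp)
    xw <- vapply(1:6, function(w) {
      lpw <- unname(a["intercept"] + a["xer_baseline"] * lat$xer_baseline +
                    a["dose_gy"] * lat$dose * (w / 6))
      rbinom(1, 1, plogis(lpw))
    }, integer(1))
    list(xer_12m = rbinom(1, 1, p12),
         xer_6m = rbinom(1, 1, plogis(lp + config$xer_6m_shift)),
         xer_weekly = xw, p12 = p12)
  })
  volumes <- NULL
  if (keep_images) {
    volumes <- lapply(0:6, function(w)
      synthesize_intensities(masks[[w + 1]], config$texture_params,
                             if (w == 0) config$contrast_offset_hu else 0,
                             seed = child_seed(config$rng_seed, 404, i, w)))
  }
  list(
    clinical = tibble::tibble(
      patient_id = i, dose_gy = lat$dose, xer_baseline = lat$xer_baseline,
      xer_w1 = out$xer_weekly[1], xer_w2 = out$xer_weekly[2],
      xer_w3 = out$xer_weekly[3], xer_w4 = out$xer_weekly[4],
      xer_w5 = out$xer_weekly[5], xer_w6 = out$xer_weekly[6],
      xer_6m = out$xer_6m, xer_12m = out$xer_12m),
    truth = tibble::tibble(
      patient_id = i, dose_gy = lat$dose,
      shrink_w1 = lat$shrink[1], shrink_w2 = lat$shrink[2],
      shrink_w3 = lat$shrink[3], shrink_w4 = lat$shrink[4],
      shrink_w5 = lat$shrink[5], shrink_w6 = lat$shrink[6],
      surface0_cm2 = s0, delta_surface_w3_cm2 = dsurf3,
      linear_predictor = lp, p_event = out$p12),
    masks = masks, volumes = volumes)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws the full cohort: per patient a planning mask and six weekly masks
#' with cumulative dose-driven noisy shrinkage, CT-like intensities per scan
#' (contrast offset on the planning scan only), baseline xerostomia, weekly
#' acute xerostomia, and 6-/12-month outcomes from the logistic truth. The
#' ground-truth latents (shrink fractions, true week-3 surface change, linear
#' predictor, outcome probability) are returned alongside.
#'
#' @param config [cohort_config()]
#' @param keep_images keep masks/volumes in memory (set `FALSE` for large
#'   cohorts where only clinical + truth tables are needed downstream via
#'   [extract_cohort_features()]).
#' @return list of class `synthetic_cohort`: `clinical` (tibble), `truth`
#'   (tibble), `patients` (list of per-patient masks/volumes or `NULL`),
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), keep_images = TRUE) {
  pts <- lapply(seq_len(config$n_patients), function(i) {
    p <- generate_patient(config, i, keep_images = keep_images)
    if (!keep_images) p[c("clinical", "truth")] else p
  })
  structure(list(
    clinical = dplyr::bind_rows(lapply(pts, `[[`, "clinical")),
    truth = dplyr::bind_rows(lapply(pts, `[[`, "truth")),
    patients = if (keep_images)
      lapply(pts, function(p) p[c("masks", "volumes")]) else NULL,
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$clinical), " patients, ",
      "event rate (12m) ", round(mean(x$clinical$xer_12m), 3),
      if (is.null(x$patients)) ", images not retained" else ", images retained",
      "\n", sep = "")
  invisible(x)
}

#' Fast tabular surrogate of the imaging cohort
#'
#' Shares the latent model of [generate_cohort()] (dose, baseline status,
#' weekly noisy dose-linked shrinkage, logistic outcome on the week-3 surface
#' change) but replaces the voxel pipeline with the analytic ellipsoid
#' surface: `dS = S0 * ((V3/V0)^(2/3) - 1)`. Intended for large-n parameter
#' recovery and calibration checks where image synthesis is unnecessary.
#'
#' @param n number of patients
#' @param config [cohort_config()] providing the latent parameters
#' @param seed integer seed (defaults to the config seed)
#' @return tibble with dose, baseline status, true week-3 surface change,
#'   true probability and the binary 12-month outcome
#' @export
simulate_clinical_cohort <- function(n, config = cohort_config(), seed = NULL) {
  seed <- seed %||% config$rng_seed
  ax <- config$semiaxes_mm / 10   # cm
  p_ <- 1.6075                    # Thomsen approximation to ellipsoid area
  s_template <- 4 * pi * (((ax[1] * ax[2])^p_ + (ax[1] * ax[3])^p_ +
                           (ax[2] * ax[3])^p_) / 3)^(1 / p_)
  b <- config$outcome_betas
  with_seed(seed, {
    dose <- pmin(pmax(rnorm(n, config$dose_mean_gy, config$dose_sd_gy), 1), 75)
    xer0 <- rbinom(n, 1, config$baseline_xer_prevalence)
    scale <- 1 + runif(n, -config$size_jitter, config$size_jitter)
    s0 <- s_template * scale^2
    shr <- matrix(pmax(-0.05, rnorm(3 * n, config$shrink_dose_slope * dose,
                                    config$shrink_noise_sd)), n, 3)
    vratio <- apply(1 - shr, 1, prod)
    dsurf <- s0 * (vratio^(2 / 3) - 1)
    lp <- unname(b["intercept"] + b["xer_baseline"] * xer0 +
                 b["dose_gy"] * dose + b["delta_surface_cm2"] * dsurf)
    tibble::tibble(patient_id = seq_len(n), dose_gy = dose, xer_baseline = xer0,
                   volume_ratio_w3 = vratio,
                   delta_surface_w3_cm2 = dsurf, linear_predictor = lp,
                   p_event = plogis(lp), xer_12m = rbinom(n, 1, plogis(lp)))
  })
}

#' Extract the radiomics feature table for a whole cohort
#'
#' Streams patients: images are (re)generated one patient at a time from the
#' config and discarded after extraction, so memory stays flat for large
#' cohorts. For a cohort generated with `keep_images = TRUE` the retained
#' images are used directly.
#'
#' @param cohort a `synthetic_cohort` (or a [cohort_config()], in which case
#'   the cohort is generated on the fly)
#' @param bin_width_hu discretization bin width for texture features
#' @return tibble: `patient_id`, `week` (0 = planning), `feature`, `family`,
#'   `value`, `unit`
#' @export
extract_cohort_features <- function(cohort, bin_width_hu = 25) {
  if (inherits(cohort, "cohort_config"))
    cohort <- list(config = cohort, patients = NULL,
                   clinical = tibble::tibble(patient_id = seq_len(cohort$n_patients)))
  cfg <- cohort$config
  one <- function(i) {
    pat <- if (!is.null(cohort$patients)) cohort$patients[[i]]
           else generate_patient(cfg, i, keep_images = TRUE)
    dplyr::bind_rows(lapply(0:6, function(w) {
      ft <- extract_features(pat$volumes[[w + 1]], pat$masks[[w + 1]],
                             bin_width_hu = bin_width_hu)
      dplyr::mutate(ft, patient_id = i, week = w, .before = 1)
    }))
  }
  dplyr::bind_rows(lapply(cohort$clinical$patient_id, one))
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks as NIfTI (`patient<i>_week<w>_{ct,mask}.nii.gz`), the
#' clinical table as CSV, the ground truth as JSON.
#'
#' @param cohort `synthetic_cohort` generated with `keep_images = TRUE`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$patients))
    stop("cohort was generated with keep_images = FALSE", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    for (w in 0:6) {
      write_volume(p$volumes[[w + 1]],
                   file.path(dir, sprintf("patient%03d_week%d_ct.nii.gz", i, w)))
      write_volume(p$masks[[w + 1]],
                   file.path(dir, sprintf("patient%03d_week%d_mask.nii.gz", i, w)))
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
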