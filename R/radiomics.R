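#' Geometric (shape) features of a 3D ROI
#'
#' Computes shape descriptors of a binary ROI on its physical voxel lattice:
#' volume, mesh surface area, surface-to-volume ratio, compactness measures,
#' sphericity, bounding-box volume, maximum 3D diameter and principal-axis
#' lengths. Surface area is measured on a triangulated iso-surface of the
#' lightly smoothed signed Euclidean distance field of the mask (level 0),
#' which suppresses the staircase bias that a binary-voxel iso-surface carries
#' on smooth anatomical shapes.
#'
#' When `intensity` is supplied, the product feature `volume_x_mean_intensity`
#' (cm^3 x HU) is added, computed from the full mask.
#'
#' @param mask an [roi_mask()] (or logical 3D array; spacing then taken from
#'   `spacing_mm`).
#' @param intensity optional [volume_grid()] aligned to the mask.
#' @param spacing_mm fallback voxel spacing if `mask` carries none.
#' @return A tibble with columns `feature`, `family` (`"geometric"`), `value`
#'   and `unit`. Volumes are cm^3, surfaces cm^2, lengths mm.
#' @export
extract_geometric <- function(mask, intensity = NULL,
                              spacing_mm = c(0.94, 0.94, 2.0)) {
  sp <- spacing_of(mask, spacing_mm)
  m <- as_mask_array(mask)
  nvox <- sum(m)
  if (nvox == 0) stop("empty ROI: geometric features undefined", call. = FALSE)
  if (n_components(m, 6) > 1)
    warning("mask has multiple 6-connected components; features computed on the union")

  vox_cm3 <- prod(sp) / 1000
  volume_cm3 <- nvox * vox_cm3
  volume_mm3 <- nvox * prod(sp)
  surface_mm2 <- mesh_surface_area_mm2(m, sp)
  surface_cm2 <- surface_mm2 / 100

  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, "*")   # voxel centres, mm
  bbox_mm3 <- prod((apply(idx, 2, max) - apply(idx, 2, min) + 1) * sp)

  if (nvox > 1) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat  <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  r_eq <- (3 * volume_mm3 / (4 * pi))^(1 / 3)
  vals <- c(
    volume_cm3            = volume_cm3,
    surface_cm2           = surface_cm2,
    surface_to_volume     = surface_mm2 / volume_mm3,
    compactness1          = volume_mm3 / (sqrt(pi) * surface_mm2^1.5),
    compactness2          = 36 * pi * volume_mm3^2 / surface_mm2^3,
    sphericity            = (36 * pi * volume_mm3^2)^(1 / 3) / surface_mm2,
    spherical_disproportion = surface_mm2 / (4 * pi * r_eq^2),
    bbox_volume_cm3       = bbox_mm3 / 1000,
    max_diameter_mm       = cpp_max_diameter(as.vector(m), dim(m), sp),
    major_axis_mm         = major,
    minor_axis_mm         = minor,
    least_axis_mm         = least,
    elongation            = elong,
    flatness              = flat
  )
  units <- c("cm3", "cm2", "1/mm", "", "", "", "", "cm3", "mm", "mm", "mm", "mm", "", "")
  if (!is.null(intensity)) {
    vals <- c(vals, volume_x_mean_intensity = volume_cm3 * mean(intensity[m]))
    units <- c(units, "cm3.HU")
  }
  tibble::tibble(feature = names(vals), family = "geometric",
                 value = unname(vals), unit = units)
}

# Mesh surface area (mm^2): marching-tetrahedra iso-surface at level 0 of the
# Gaussian-smoothed (sigma 0.7 voxels) signed Euclidean distance field. ROIs
# too thin to survive the smoothing (a few voxels) fall back to the exposed
# voxel-face area so every non-empty ROI has a positive, finite surface.
mesh_surface_area_mm2 <- function(mask, spacing, pad = 3L, sigma_vox = 0.7) {
  d <- dim(mask)
  big <- array(FALSE, d + 2L * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask
  sdf <- cpp_signed_edt(as.vector(big), dim(big), spacing)
  sm <- cpp_gauss3(sdf, dim(big), rep(sigma_vox, 3))
  a <- cpp_isosurface_area(sm, dim(big), spacing, 0)
  if (a <= 0) voxel_face_area_mm2(mask, spacing) else a
}

# exposed voxel-face area (used as degenerate fallback and as a test oracle)
voxel_face_area_mm2 <- function(mask, spacing) {
  d <- dim(mask)
  pads <- function(axis) {
    padded <- array(FALSE, d + c(axis == 1, axis == 2, axis == 3))
    padded
  }
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  total <- 0
  for (axis in 1:3) {
    p <- pads(axis)
    idx_lo <- idx_hi <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_hi[[axis]] <- idx_hi[[axis]] + 1
    lo <- p; lo[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]] <- mask
    hi <- p; hi[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] <- mask
    total <- total + sum(xor(lo, hi)) * face[axis]
  }
  total
}

#' First-order intensity features of a ROI
#'
#' @param volume a [volume_grid()] (HU).
#' @param mask an [roi_mask()] aligned to the volume.
#' @param excluded_slices axial slice indices to drop before extraction
#'   (metal-artefact handling); defaults to the mask's `artifact_slices`.
#' @param bin_width_hu bin width used for the histogram entropy (HU).
#' @return tibble of `feature`, `family = "intensity"`, `value`, `unit`.
#'   Kurtosis is reported in the Pearson convention (a normal distribution
#'   gives 3, not 0).
#' @export
extract_intensity <- function(volume, mask, excluded_slices = NULL,
                              bin_width_hu = 25) {
  if (is.null(excluded_slices))
    excluded_slices <- attr(mask, "artifact_slices") %||% integer(0)
  m <- drop_slices(as_mask_array(mask), excluded_slices)
  if (!any(m)) stop("ROI empty after artefact exclusion", call. = FALSE)
  v <- as.numeric(volume[m])
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2); m3 <- mean((v - mu)^3); m4 <- mean((v - mu)^4)
  qs <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  inner <- v[v >= qs[1] & v <= qs[4]]
  dro <- discretize(volume, roi_mask(m, spacing_of(mask)), bin_width_hu)
  p <- tabulate(dro$levels[m], nbins = dro$n_levels)
  p <- p[p > 0] / n
  vals <- c(
    mean = mu,
    median = stats::median(v),
    variance = if (n > 1) stats::var(v) else 0,
    sd = if (n > 1) stats::sd(v) else 0,
    min = min(v),
    max = max(v),
    p10 = qs[1],
    p90 = qs[4],
    iqr = qs[3] - qs[2],
    range = max(v) - min(v),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(v^2),
    rms = sqrt(mean(v^2)),
    entropy = -sum(p * log2(p)),
    mean_abs_dev = mean(abs(v - mu)),
    robust_mean_abs_dev = mean(abs(inner - mean(inner)))
  )
  tibble::tibble(feature = names(vals), family = "intensity",
                 value = unname(vals),
                 unit = c(rep("HU", 10), "", "", "HU2", "HU", "bit", "HU", "HU"))
}

drop_slices <- function(mask, slices) {
  if (length(slices)) mask[, , intersect(seq_len(dim(mask)[3]), slices)] <- FALSE
  mask
}

#' Discretize ROI intensities to integer grey levels
#'
#' Fixed-bin-width discretization anchored at the ROI minimum:
#' `level(v) = floor((v - min_roi) / bin_width) + 1`. Levels are 1..N_g inside
#' the ROI and 0 outside. Adding a constant to all intensities leaves the
#' levels unchanged.
#'
#' @param volume [volume_grid()]
#' @param mask [roi_mask()]
#' @param bin_width_hu positive bin width in HU (default 25)
#' @return object of class `discretized_roi`: list with `levels` (integer 3D
#'   array), `n_levels`, `bin_width_hu`, `min_hu`, `n_voxels`.
#' @export
discretize <- function(volume, mask, bin_width_hu = 25) {
  if (!is.numeric(bin_width_hu) || length(bin_width_hu) != 1 || bin_width_hu <= 0)
    stop("`bin_width_hu` must be a single positive number", call. = FALSE)
  m <- as_mask_array(mask)
  if (!any(m)) stop("empty ROI cannot be discretized", call. = FALSE)
  lev <- array(0L, dim = dim(m))
  v <- as.numeric(volume[m])
  lev[m] <- as.integer(floor((v - min(v)) / bin_width_hu)) + 1L
  structure(list(levels = lev, n_levels = max(lev), bin_width_hu = bin_width_hu,
                 min_hu = min(v), n_voxels = sum(m)),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat("<discretized_roi> ", x$n_voxels, " voxels, ", x$n_levels,
      " grey levels (bin ", x$bin_width_hu, " HU)\n", sep = "")
  invisible(x)
}

texture_tbl <- function(vals, prefix) {
  tibble::tibble(feature = paste0(prefix, "_", names(vals)), family = "texture",
                 value = unname(vals), unit = "")
}

#' Grey-level co-occurrence matrix features
#'
#' Symmetric co-occurrence matrices over the 13 unique 3D lattice directions
#' at distance 1, normalised per direction and then averaged. For a ROI with a
#' single grey level the correlation is defined as 0 (zero-variance
#' convention); all other features follow their standard probability-matrix
#' definitions.
#'
#' @param droi a `discretized_roi` from [discretize()]
#' @return tibble of GLCM features (family `"texture"`)
#' @export
glcm_features <- function(droi) {
  ng <- droi$n_levels
  P <- cpp_glcm(as.vector(droi$levels), dim(droi$levels), ng)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s2_i <- sum((i - mu_i)^2 * P); s2_j <- sum((j - mu_j)^2 * P)
  corr <- if (s2_i > 0 && s2_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(s2_i * s2_j) else 0
  pn <- P[P > 0]
  vals <- c(
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    joint_entropy = -sum(pn * log2(pn)),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * P),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * P)
  )
  texture_tbl(vals, "glcm")
}

#' Grey-level run-length matrix features
#'
#' Run matrices over the 13 unique 3D directions, counts averaged across
#' directions before feature computation.
#'
#' @inheritParams glcm_features
#' @return tibble of GLRLM features
#' @export
glrlm_features <- function(droi) {
  R <- cpp_glrlm(as.vector(droi$levels), dim(droi$levels), droi$n_levels)
  nr <- sum(R)
  i <- row(R); l <- col(R)
  ri <- rowSums(R); rl <- colSums(R)
  vals <- c(
    sre = sum(R / l^2) / nr,
    lre = sum(R * l^2) / nr,
    gln = sum(ri^2) / nr,
    rln = sum(rl^2) / nr,
    rp = nr / droi$n_voxels,
    lgre = sum(R / i^2) / nr,
    hgre = sum(R * i^2) / nr,
    srlge = sum(R / (i^2 * l^2)) / nr,
    srhge = sum(R * i^2 / l^2) / nr,
    lrlge = sum(R * l^2 / i^2) / nr,
    lrhge = sum(R * i^2 * l^2) / nr
  )
  texture_tbl(vals, "glrlm")
}

#' Grey-level size-zone matrix features
#'
#' Zones are 26-connected components of equal grey level. Includes the
#' large-zone low-grey-level emphasis (LZLGE) weighting large zones of low
#' level.
#'
#' @inheritParams glcm_features
#' @return tibble of GLSZM features
#' @export
glszm_features <- function(droi) {
  Z <- cpp_glszm(as.vector(droi$levels), dim(droi$levels), droi$n_levels)
  nz <- sum(Z)
  i <- row(Z); s <- col(Z)
  vals <- c(
    sze = sum(Z / s^2) / nz,
    lze = sum(Z * s^2) / nz,
    lgze = sum(Z / i^2) / nz,
    hgze = sum(Z * i^2) / nz,
    szlge = sum(Z / (i^2 * s^2)) / nz,
    szhge = sum(Z * i^2 / s^2) / nz,
    lzlge = sum(Z * s^2 / i^2) / nz,
    lzhge = sum(Z * i^2 * s^2) / nz,
    zone_percentage = nz / droi$n_voxels
  )
  texture_tbl(vals, "glszm")
}

#' Neighbourhood grey-tone difference matrix features
#'
#' 26-neighbourhood mean-difference matrix over in-ROI voxels that have at
#' least one in-ROI neighbour. Coarseness is `1 / (eps + sum(p_i * s_i))` with
#' `eps = 1e-6`, so a perfectly uniform ROI yields the capped value `1e6`.
#'
#' @inheritParams glcm_features
#' @return tibble of NGTDM features
#' @export
ngtdm_features <- function(droi) {
  M <- cpp_ngtdm(as.vector(droi$levels), dim(droi$levels), droi$n_levels)
  s_i <- M[, 1]; n_i <- M[, 2]
  N <- sum(n_i)
  eps <- 1e-6
  if (N == 0) {   # e.g. scattered single voxels with no in-ROI neighbours
    vals <- c(coarseness = 1 / eps, contrast = 0, busyness = 0,
              complexity = 0, strength = 0)
    return(texture_tbl(vals, "ngtdm"))
  }
  p_i <- n_i / N
  lev <- seq_along(p_i)
  act <- which(p_i > 0)
  ngp <- length(act)
  ii <- rep(lev[act], each = ngp); jj <- rep(lev[act], times = ngp)
  pi_ <- rep(p_i[act], each = ngp); pj_ <- rep(p_i[act], times = ngp)
  si_ <- rep(s_i[act], each = ngp); sj_ <- rep(s_i[act], times = ngp)
  contrast <- if (ngp > 1)
    (sum(pi_ * pj_ * (ii - jj)^2) / (ngp * (ngp - 1))) * (sum(s_i) / N) else 0
  denom_b <- sum(abs(ii * pi_ - jj * pj_))
  vals <- c(
    coarseness = 1 / (eps + sum(p_i * s_i)),
    contrast = contrast,
    busyness = if (denom_b > 0) sum(p_i * s_i) / denom_b else 0,
    complexity = sum(abs(ii - jj) * (pi_ * si_ + pj_ * sj_) / (pi_ + pj_)) / N,
    strength = sum((pi_ + pj_) * (ii - jj)^2) / (eps + sum(s_i))
  )
  texture_tbl(vals, "ngtdm")
}

#' Extract the full feature catalogue for one scan
#'
#' Geometric features are computed on the complete mask; intensity and texture
#' features on the mask after artefact-slice exclusion, following the
#' convention that metal-artefact slices corrupt intensities but not the
#' delineated shape.
#'
#' @param volume [volume_grid()]
#' @param mask [roi_mask()] (its `artifact_slices` attribute, if any, drives
#'   the exclusion)
#' @param bin_width_hu texture/entropy discretization bin width (HU)
#' @return tibble with columns `feature`, `family`, `value`, `unit`
#' @export
extract_features <- function(volume, mask, bin_width_hu = 25) {
  excl <- attr(mask, "artifact_slices") %||% integer(0)
  geo <- extract_geometric(mask, intensity = volume)
  m_t <- drop_slices(as_mask_array(mask), excl)
  if (!any(m_t)) stop("ROI empty after artefact exclusion", call. = FALSE)
  mt <- roi_mask(m_t, spacing_of(mask))
  intens <- extract_intensity(volume, mt, excluded_slices = integer(0),
                              bin_width_hu = bin_width_hu)
  dro <- discretize(volume, mt, bin_width_hu)
  dplyr::bind_rows(geo, intens, glcm_features(dro), glrlm_features(dro),
                   glszm_features(dro), ngtdm_features(dro))
}

#' Names of all features in the extraction catalogue, by family
#' @return named list of character vectors (`geometric`, `intensity`, `texture`)
#' @export
feature_catalogue <- function() {
  list(
    geometric = c("volume_cm3", "surface_cm2", "surface_to_volume",
                  "compactness1", "compactness2", "sphericity",
                  "spherical_disproportion", "bbox_volume_cm3",
                  "max_diameter_mm", "major_axis_mm", "minor_axis_mm",
                  "least_axis_mm", "elongation", "flatness",
                  "volume_x_mean_intensity"),
    intensity = c("mean", "median", "variance", "sd", "min", "max", "p10",
                  "p90", "iqr", "range", "skewness", "kurtosis", "energy",
                  "rms", "entropy", "mean_abs_dev", "robust_mean_abs_dev"),
    texture = c(paste0("glcm_", c("contrast", "correlation", "joint_entropy",
                                  "energy", "homogeneity", "dissimilarity",
                                  "cluster_shade", "cluster_prominence")),
                paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre",
                                   "hgre", "srlge", "srhge", "lrlge", "lrhge")),
                paste0("glszm_", c("sze", "lze", "lgze", "hgze", "szlge",
                                   "szhge", "lzlge", "lzhge", "zone_percentage")),
                paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                   "complexity", "strength")))
  )
}
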