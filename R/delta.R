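#' Remove metal-artefact slices before intensity/texture extraction
#'
#' Flagged axial slices are removed from the mask (the volume itself is kept;
#' only the ROI membership changes). Geometric features are by convention
#' computed on the full mask, so callers apply this only to the
#' intensity/texture path.
#'
#' @param volume [volume_grid()]
#' @param mask [roi_mask()]
#' @param flags integer axial slice indices, or a logical vector over slices
#' @return list with elements `volume` (unchanged) and `mask` (slices removed)
#' @export
exclude_artifact_slices <- function(volume, mask, flags) {
  if (is.logical(flags)) flags <- which(flags)
  m <- drop_slices(as_mask_array(mask), as.integer(flags))
  if (!any(m)) stop("ROI empty after artefact exclusion", call. = FALSE)
  list(volume = volume, mask = roi_mask(m, spacing_of(mask)))
}

check_catalogue <- function(f_a, f_b) {
  miss <- c(setdiff(f_a$feature, f_b$feature), setdiff(f_b$feature, f_a$feature))
  if (length(miss))
    stop("feature catalogue mismatch: ", paste(unique(miss), collapse = ", "),
         call. = FALSE)
}

#' Geometric delta: weekly scan minus the planning scan
#'
#' Sign convention is later-minus-baseline, so gland shrinkage gives a
#' negative surface/volume change (a larger reduction is a more negative
#' delta, consistent with an odds ratio below 1 for risk increasing with
#' reduction).
#'
#' @param f_week feature tibble (`feature`, `value`) of the weekly scan
#' @param f_planning feature tibble of the planning (week-0) scan
#' @return tibble `feature`, `delta`
#' @export
geometric_delta <- function(f_week, f_planning) {
  check_catalogue(f_week, f_planning)
  base <- f_planning$value[match(f_week$feature, f_planning$feature)]
  tibble::tibble(feature = f_week$feature, delta = f_week$value - base)
}

#' Intensity/texture delta: weekly scan minus the week-1 scan
#'
#' The planning scan is contrast-enhanced and never enters an
#' intensity/texture delta; week 1 (pre-contrast-free) is the baseline, so
#' only weeks 2..6 are valid.
#'
#' @param f_week feature tibble of the weekly scan (weeks 2..6)
#' @param f_week1 feature tibble of the week-1 baseline scan
#' @param week integer week index of `f_week`
#' @return tibble `feature`, `delta`
#' @export
texture_delta <- function(f_week, f_week1, week) {
  if (!week %in% 2:6)
    stop("intensity/texture deltas are defined for weeks 2..6 only ",
         "(the contrast-enhanced planning scan and the week-1 baseline ",
         "cannot be delta'd against week 1)", call. = FALSE)
  check_catalogue(f_week, f_week1)
  base <- f_week1$value[match(f_week$feature, f_week1$feature)]
  tibble::tibble(feature = f_week$feature, delta = f_week$value - base)
}

#' Proportional delta relative to the baseline magnitude
#'
#' `(f_week - f_base) / |f_base|`; features with a zero baseline get `NA`
#' (with a warning) rather than an infinite value.
#'
#' @param f_week,f_base feature tibbles (`feature`, `value`)
#' @return tibble `feature`, `delta`
#' @export
proportional_delta <- function(f_week, f_base) {
  check_catalogue(f_week, f_base)
  base <- f_base$value[match(f_week$feature, f_base$feature)]
  zero <- base == 0
  if (any(zero))
    warning("zero baseline for: ", paste(f_week$feature[zero], collapse = ", "),
            "; proportional delta set to NA")
  d <- (f_week$value - base) / abs(base)
  d[zero] <- NA_real_
  tibble::tibble(feature = f_week$feature, delta = d)
}

#' Weekly delta-feature table with asymmetric baselines
#'
#' Builds the per-patient, per-week delta features from a long feature table:
#' geometric features are differenced against the planning scan (week 0),
#' intensity and texture features against the week-1 scan; deltas exist for
#' weeks 2..6 and only where both scans of the pair are present.
#'
#' @param features long tibble from [extract_cohort_features()]
#'   (`patient_id`, `week`, `feature`, `family`, `value`)
#' @param mode `"absolute"` (later minus baseline) or `"proportional"`
#'   (relative to the baseline magnitude)
#' @return tibble `patient_id`, `week`, `feature`, `family`, `delta`, `mode`
#' @export
delta_features <- function(features, mode = c("absolute", "proportional")) {
  mode <- match.arg(mode)
  base_week <- dplyr::mutate(
    features, base_week = ifelse(.data$family == "geometric", 0L, 1L))
  baselines <- dplyr::filter(base_week, .data$week == .data$base_week)
  baselines <- dplyr::select(baselines, "patient_id", "feature",
                             base_value = "value", "base_week")
  weekly <- dplyr::filter(base_week, .data$week %in% 2:6)
  joined <- dplyr::inner_join(weekly, baselines,
                              by = c("patient_id", "feature", "base_week"))
  out <- dplyr::mutate(
    joined,
    delta = if (mode == "absolute") .data$value - .data$base_value
            else ifelse(.data$base_value == 0, NA_real_,
                        (.data$value - .data$base_value) / abs(.data$base_value)),
    mode = mode)
  dplyr::select(out, "patient_id", "week", "feature", "family", "delta", "mode")
}

#' Pivot one week of deltas to a patients-by-features matrix
#'
#' @param deltas tibble from [delta_features()]
#' @param week_i week to extract (2..6)
#' @param families feature families to keep
#' @return wide tibble: `patient_id` plus one column per delta feature
#' @export
delta_matrix <- function(deltas, week_i,
                         families = c("geometric", "intensity", "texture")) {
  d <- dplyr::filter(deltas, .data$week == week_i, .data$family %in% families)
  tidyr::pivot_wider(dplyr::select(d, "patient_id", "feature", "delta"),
                     names_from = "feature", values_from = "delta")
}
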