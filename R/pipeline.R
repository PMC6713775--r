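#' Study configuration for the end-to-end analysis
#'
#' One master seed drives cohort generation, bootstrap selection and internal
#' validation through derived child seeds, so a full run is reproducible from
#' `(config, seed)` alone.
#'
#' @param cohort [cohort_config()] for the synthetic cohort (ignored when a
#'   pre-built cohort is passed to [run_full_analysis()])
#' @param split_fraction training fraction of the enrolment-ordered split
#' @param endpoint `"xer_12m"` (primary) or `"xer_6m"` (secondary)
#' @param multivariable_week week whose selected delta-feature enters the
#'   multivariable models (default 3)
#' @param selection [selection_config()]
#' @param validation_B bootstrap replicates for internal validation
#' @param bin_width_hu texture discretization bin width
#' @param seed master seed
#' @return object of class `study_config`
#' @export
study_config <- function(cohort = NULL, split_fraction = 0.8,
                         endpoint = c("xer_12m", "xer_6m"),
                         multivariable_week = 3,
                         selection = NULL, validation_B = 1000,
                         bin_width_hu = 25, seed = 1L) {
  endpoint <- match.arg(endpoint)
  stopifnot(split_fraction > 0, split_fraction < 1,
            multivariable_week %in% 2:6)
  cohort <- cohort %||% cohort_config(rng_seed = child_seed(seed, 11))
  selection <- selection %||% selection_config(rng_seed = child_seed(seed, 22))
  structure(list(cohort = cohort, split_fraction = split_fraction,
                 endpoint = endpoint, multivariable_week = multivariable_week,
                 selection = selection, validation_B = validation_B,
                 bin_width_hu = bin_width_hu, seed = as.integer(seed),
                 validation_seed = child_seed(seed, 33)),
            class = "study_config")
}

#' Deterministic ordered cohort split
#'
#' Splits by position after ordering on `key` (enrolment order when `key` is
#' `NULL`): the first `floor(fraction * n)` patients train, the rest test.
#'
#' @param clinical patient-level tibble
#' @param fraction training fraction in (0, 1)
#' @param key optional ordering column name
#' @return list with `train` and `test` tibbles (disjoint, union = input)
#' @export
split_cohort <- function(clinical, fraction = 0.8, key = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(key)) clinical <- dplyr::arrange(clinical, .data[[key]])
  n <- nrow(clinical)
  n_train <- floor(fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("split leaves an empty side (n = ", n, ", fraction = ", fraction, ")",
         call. = FALSE)
  list(train = clinical[seq_len(n_train), , drop = FALSE],
       test = clinical[(n_train + 1):n, , drop = FALSE])
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = if (k == 0) 0 else max(0, ctr - hw),
    high = if (k == n) 1 else min(1, ctr + hw))
}

#' Toxicity incidence curves split at the median delta-feature
#'
#' Patients are grouped by whether their delta-feature value lies at/below or
#' above the cohort median (for a shrinkage feature the at/below group is the
#' larger-reduction group); per time point the observed incidence and Wilson
#' 95% CI are reported.
#'
#' @param data patient tibble containing `delta_col` and the timepoint columns
#' @param delta_col name of the delta-feature column to split on
#' @param timepoints character vector of binary outcome columns, in display
#'   order
#' @return tibble of class `incidence_curve`: `group`, `timepoint`,
#'   `incidence`, `ci_low`, `ci_high`, `n`
#' @export
incidence_by_median_split <- function(data, delta_col,
                                      timepoints = c("xer_baseline",
                                                     paste0("xer_w", 1:6),
                                                     "xer_6m", "xer_12m")) {
  v <- data[[delta_col]]
  if (is.null(v)) stop("column `", delta_col, "` not found", call. = FALSE)
  med <- stats::median(v)
  if (all(v == med))
    stop("delta values are all equal; median split is degenerate", call. = FALSE)
  grp <- ifelse(v <= med, "reduction >= median", "reduction < median")
  timepoints <- intersect(timepoints, names(data))
  rows <- lapply(unique(grp), function(g) {
    d <- data[grp == g, , drop = FALSE]
    dplyr::bind_rows(lapply(timepoints, function(tp) {
      k <- sum(d[[tp]]); n <- nrow(d)
      ci <- wilson_ci(k, n)
      tibble::tibble(group = g, timepoint = tp, incidence = k / n,
                     ci_low = ci[["low"]], ci_high = ci[["high"]], n = n)
    }))
  })
  out <- dplyr::bind_rows(rows)
  out$timepoint <- factor(out$timepoint, levels = timepoints)
  class(out) <- c("incidence_curve", class(out))
  out
}

# selection-aware fitting closure used for internal validation of the
# delta-feature models: the forward selection over candidate deltas is
# re-run inside every bootstrap resample.
make_selection_fit_fun <- function(endpoint, base_predictors, candidates,
                                   sel_cfg) {
  function(d) {
    X <- as.matrix(d[, candidates, drop = FALSE])
    Xz <- suppressWarnings(zscore_normalise(X))
    y <- as.numeric(d[[endpoint]])
    sel <- character(0)
    if (ncol(Xz) > 0 && length(unique(y)) == 2) {
      kept <- correlation_prefilter(Xz, y, sel_cfg$correlation_threshold)
      sel <- forward_select(Xz[, kept, drop = FALSE], y, sel_cfg$forward_alpha)
    }
    fit_logistic(d, endpoint, c(base_predictors, as.character(sel)))
  }
}

#' Run the full delta-radiomics NTCP analysis
#'
#' Simulate (or accept) a longitudinal cohort, extract features, build weekly
#' delta-features, bootstrap the variable selection per week on the training
#' set, fit the pre-treatment reference model and the delta-feature models,
#' test them on the held-out set, refit on the entire cohort and correct for
#' optimism by bootstrap internal validation, and produce median-split
#' incidence curves and weekly dose-vs-delta regressions.
#'
#' @param config [study_config()]
#' @param cohort optional pre-generated `synthetic_cohort`; by default the
#'   cohort defined by `config$cohort` is generated
#' @param features optional pre-extracted long feature table
#' @return object of class `delta_study` (a list of result tibbles and models)
#' @export
run_full_analysis <- function(config = study_config(), cohort = NULL,
                              features = NULL) {
  cfg <- config
  cohort <- cohort %||% generate_cohort(cfg$cohort, keep_images = FALSE)
  clinical <- cohort$clinical
  features <- features %||% extract_cohort_features(
    if (is.null(cohort$patients)) cfg$cohort else cohort,
    bin_width_hu = cfg$bin_width_hu)
  deltas <- delta_features(features, mode = "absolute")

  split <- split_cohort(clinical, cfg$split_fraction)
  train_ids <- split$train$patient_id
  endpoint <- cfg$endpoint

  groups <- list(geometric = "geometric",
                 intensity_texture = c("intensity", "texture"))
  sel_rows <- list(); scan_rows <- list()
  for (w in 2:6) {
    dm <- delta_matrix(deltas, w)
    dm_train <- dm[dm$patient_id %in% train_ids, , drop = FALSE]
    y_train <- split$train[[endpoint]][match(dm_train$patient_id,
                                             split$train$patient_id)]
    for (gname in names(groups)) {
      feats <- unique(deltas$feature[deltas$family %in% groups[[gname]]])
      Xw <- as.matrix(dm_train[, intersect(feats, names(dm_train)), drop = FALSE])
      scfg <- cfg$selection
      scfg$rng_seed <- child_seed(cfg$selection$rng_seed, w,
                                  match(gname, names(groups)))
      freq <- bootstrap_selection(Xw, y_train, scfg)
      sel_rows[[paste(w, gname)]] <- dplyr::mutate(freq, week = w,
                                                   group = gname, .before = 1)
      Xz <- suppressWarnings(zscore_normalise(Xw))
      sc <- univariable_scan(Xz, y_train)
      scan_rows[[paste(w, gname)]] <- dplyr::mutate(sc, week = w,
                                                    group = gname, .before = 1)
    }
  }
  selection_freq <- dplyr::bind_rows(sel_rows)
  univariable <- dplyr::bind_rows(scan_rows)

  # delta-feature entering the multivariable models: most frequently selected
  # geometric feature in the configured week
  w3 <- cfg$multivariable_week
  top_geo <- dplyr::filter(selection_freq, .data$week == w3,
                           .data$group == "geometric")
  top_feature <- top_geo$feature[1]
  delta_col <- paste0("delta_", top_feature, "_w", w3)

  dmw <- delta_matrix(deltas, w3)
  clinical[[delta_col]] <- dmw[[top_feature]][match(clinical$patient_id,
                                                    dmw$patient_id)]
  split <- split_cohort(clinical, cfg$split_fraction)

  specs <- list(
    pre_treatment = c("xer_baseline", "dose_gy"),
    delta_model_1 = c("xer_baseline", delta_col),
    delta_model_2 = c("xer_baseline", "dose_gy", delta_col))
  train_models <- lapply(specs, function(pr)
    fit_logistic(split$train, endpoint, pr))
  perf <- dplyr::bind_rows(lapply(names(specs), function(mn) {
    dplyr::bind_rows(
      dplyr::mutate(performance_report(train_models[[mn]], split$train,
                                       "apparent"), model = mn),
      dplyr::mutate(performance_report(train_models[[mn]], split$test,
                                       "test"), model = mn))
  }))
  lrt <- likelihood_ratio_test(train_models$pre_treatment,
                               train_models$delta_model_2)

  # final coefficients on the entire cohort, with optimism correction
  geo_feats <- intersect(unique(deltas$feature[deltas$family == "geometric"]),
                         names(dmw))
  cand_cols <- paste0("delta_", geo_feats, "_w", w3)
  for (j in seq_along(geo_feats))
    clinical[[cand_cols[j]]] <- dmw[[geo_feats[j]]][match(clinical$patient_id,
                                                          dmw$patient_id)]
  fit_funs <- list(
    pre_treatment = function(d) fit_logistic(d, endpoint, specs$pre_treatment),
    delta_model_1 = make_selection_fit_fun(endpoint, "xer_baseline",
                                           cand_cols, cfg$selection),
    delta_model_2 = make_selection_fit_fun(endpoint,
                                           c("xer_baseline", "dose_gy"),
                                           cand_cols, cfg$selection))
  final_models <- lapply(specs, function(pr) fit_logistic(clinical, endpoint, pr))
  validations <- lapply(names(specs), function(mn) {
    iv <- internal_validate(
      function(d) tryCatch(fit_funs[[mn]](d),
                           error = function(e) fit_logistic(d, endpoint,
                                                            specs[[mn]])),
      clinical, B = cfg$validation_B,
      seed = child_seed(cfg$validation_seed, match(mn, names(specs))))
    # corrected coefficients attach to the full-cohort model of that spec
    m <- final_models[[mn]]
    shrunk <- m$coefficients
    shrunk[names(shrunk) != "(Intercept)"] <-
      shrunk[names(shrunk) != "(Intercept)"] * iv$calibration_slope
    X <- as.matrix(clinical[, m$predictors, drop = FALSE])
    off <- as.vector(X %*% shrunk[m$predictors])
    refit <- suppressWarnings(stats::glm(clinical[[endpoint]] ~ 1 + offset(off),
                                         family = stats::binomial()))
    shrunk["(Intercept)"] <- stats::coef(refit)[1]
    m$corrected <- shrunk
    list(model = m, validation = iv)
  })
  names(validations) <- names(specs)

  coef_table <- dplyr::bind_rows(lapply(names(specs), function(mn) {
    m <- validations[[mn]]$model
    ors <- odds_ratios(m)
    tibble::tibble(model = mn, term = names(m$coefficients),
                   beta = unname(m$coefficients),
                   beta_corrected = unname(m$corrected),
                   or = c(NA_real_, ors$or),
                   ci_low = c(NA_real_, ors$ci_low),
                   ci_high = c(NA_real_, ors$ci_high))
  }))

  incidence <- incidence_by_median_split(clinical, delta_col)
  dose_reg <- dplyr::bind_rows(lapply(2:6, function(w) {
    dmx <- delta_matrix(deltas, w)
    dd <- dplyr::inner_join(
      dplyr::select(clinical, "patient_id", "dose_gy"),
      dplyr::select(dmx, "patient_id", dplyr::all_of(top_feature)),
      by = "patient_id")
    lf <- fit_linear(dd, "dose_gy", top_feature)
    dplyr::mutate(glance(lf), week = w, feature = top_feature, .before = 1)
  }))

  structure(list(
    config = cfg, clinical = clinical, truth = cohort$truth, deltas = deltas,
    split = list(train_ids = train_ids,
                 test_ids = setdiff(clinical$patient_id, train_ids)),
    selection_frequency = selection_freq, univariable = univariable,
    top_feature = top_feature, delta_col = delta_col,
    train_models = train_models, performance = perf, lrt = lrt,
    final = validations, coefficients = coef_table,
    incidence = incidence, dose_regression = dose_reg),
    class = "delta_study")
}

#' @export
print.delta_study <- function(x, ...) {
  cat("<delta_study> endpoint:", x$config$endpoint,
      "| n =", nrow(x$clinical),
      "| multivariable week:", x$config$multivariable_week, "\n")
  cat("top geometric delta-feature:", x$top_feature, "\n")
  cat("\nModel coefficients (entire cohort, uncorrected | corrected):\n")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat("\nLRT delta-model-2 vs pre-treatment (train): p =",
      signif(x$lrt$p_value, 3), "\n")
  invisible(x)
}
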