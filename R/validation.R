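#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen event has a higher prediction than a
#' randomly chosen non-event, ties credited 1/2.
#'
#' @param y binary outcomes (0/1)
#' @param p predictions (any monotone score)
#' @return AUC in `[0, 1]`
#' @export
auc <- function(y, p) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required for AUC", call. = FALSE)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke's R-squared
#'
#' `[1 - exp(2 (l0 - l1) / n)] / [1 - exp(2 l0 / n)]` from the fitted and
#' intercept-only log-likelihoods.
#'
#' @param model fitted `ntcp_model` (carrying `log_lik`, `null_log_lik`, `n`),
#'   or a numeric log-likelihood when `null_log_lik`/`n` are given explicitly
#' @param null_log_lik,n intercept-only log-likelihood and sample size
#'   (taken from the model when omitted)
#' @return R-squared in `[0, 1]`
#' @export
nagelkerke_r2 <- function(model, null_log_lik = NULL, n = NULL) {
  if (inherits(model, "ntcp_model")) {
    ll1 <- model$log_lik
    ll0 <- null_log_lik %||% model$null_log_lik
    n <- n %||% model$n
  } else {
    ll1 <- model
    ll0 <- null_log_lik
  }
  if (ll1 < ll0 - 1e-8)
    stop("model log-likelihood below the null model's; fits are inconsistent",
         call. = FALSE)
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  cox_snell / (1 - exp(2 * ll0 / n))
}

#' Discrimination slope
#'
#' Mean predicted probability among events minus mean among non-events.
#'
#' @inheritParams auc
#' @return value in `[-1, 1]`
#' @export
discrimination_slope <- function(y, p) {
  y <- as.numeric(y)
  if (!any(y == 1) || !any(y == 0))
    stop("both outcome classes required", call. = FALSE)
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations by quantiles of predicted risk (tied predictions stay
#' in one group), compares observed and expected events and non-events with a
#' chi-squared statistic on `groups - 2` degrees of freedom. Groups whose
#' expected count is zero are merged into their neighbour (logged via a
#' message).
#'
#' @param y binary outcomes
#' @param p predicted probabilities
#' @param n_groups number of risk groups (default 10; must leave df >= 1)
#' @return tibble `statistic`, `df`, `p_value`, `n_groups_used`
#' @export
hosmer_lemeshow <- function(y, p, n_groups = 10) {
  y <- as.numeric(y)
  if (n_groups < 3) stop("n_groups must be >= 3 (df = n_groups - 2)", call. = FALSE)
  if (length(y) < 2 * n_groups)
    stop("need at least 2 observations per group", call. = FALSE)
  br <- unique(stats::quantile(p, seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 4) stop("predictions too tied to form >= 3 groups", call. = FALSE)
  g <- cut(p, breaks = br, include.lowest = TRUE)
  obs1 <- tapply(y, g, sum); n_g <- tapply(y, g, length)
  e1 <- tapply(p, g, sum)
  keep <- !is.na(n_g)
  obs1 <- obs1[keep]; n_g <- n_g[keep]; e1 <- e1[keep]
  e0 <- n_g - e1
  if (any(e1 == 0 | e0 == 0)) {
    message("merging Hosmer-Lemeshow group(s) with zero expected count")
    while (any(e1 == 0 | e0 == 0) && length(e1) > 3) {
      j <- which(e1 == 0 | e0 == 0)[1]
      k <- if (j == 1) 2 else j - 1
      e1[k] <- e1[k] + e1[j]; e0[k] <- e0[k] + e0[j]
      obs1[k] <- obs1[k] + obs1[j]; n_g[k] <- n_g[k] + n_g[j]
      e1 <- e1[-j]; e0 <- e0[-j]; obs1 <- obs1[-j]; n_g <- n_g[-j]
    }
  }
  stat <- sum((obs1 - e1)^2 / e1 + ((n_g - obs1) - e0)^2 / e0)
  df <- length(e1) - 2
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_groups_used = length(e1))
}

#' Apparent performance of a model on a dataset
#'
#' @param model `ntcp_model`
#' @param data data frame with the model's outcome and predictors
#' @param context label (`"apparent"`, `"internal_validation"`, `"test"`)
#' @param use_corrected evaluate the optimism-corrected coefficients
#' @return tibble `metric`, `value`, `context`
#' @export
performance_report <- function(model, data, context = "apparent",
                               use_corrected = FALSE) {
  y <- as.numeric(data[[model$outcome]])
  p <- ntcp(model, data, use_corrected = use_corrected)
  ll1 <- sum(y * log(p) + (1 - y) * log(1 - p))
  ll0 <- loglik_null(y)
  r2 <- if (ll1 >= ll0) nagelkerke_r2(ll1, ll0, length(y)) else NA_real_
  hl <- tryCatch(hosmer_lemeshow(y, p),
                 error = function(e) tibble::tibble(statistic = NA_real_,
                                                    df = NA_real_, p_value = NA_real_))
  tibble::tibble(
    metric = c("auc", "nagelkerke_r2", "discrimination_slope",
               "hosmer_lemeshow_stat", "hosmer_lemeshow_p"),
    value = c(auc(y, p), r2, discrimination_slope(y, p),
              hl$statistic[1], hl$p_value[1]),
    context = context)
}

#' Bootstrap internal validation with optimism correction
#'
#' Harrell-style validation of a whole model-building procedure: the procedure
#' (normalisation, selection, fitting - whatever `fit_fun` encloses) is re-run
#' on every bootstrap resample; each bootstrap model is scored on its resample
#' (apparent) and on the original data (test). The per-metric optimism is
#' `mean(apparent_b - test_b)`, subtracted from the original apparent
#' performance. The calibration slope of each bootstrap model's linear
#' predictor on the original data is averaged, and the corrected coefficients
#' are the original ones shrunk by that mean slope with the intercept refit
#' (slopes held fixed).
#'
#' @param fit_fun function(data) -> `ntcp_model`; must encapsulate every
#'   data-adaptive step so the resampling honestly repeats them
#' @param data original data frame
#' @param B number of bootstrap replicates (>= 2)
#' @param seed integer seed
#' @return object of class `internal_validation`: `model` (with `corrected`
#'   coefficients filled in), `apparent`, `optimism`, `corrected`,
#'   `calibration_slope`, `calibration_intercept`, `B`
#' @export
internal_validate <- function(fit_fun, data, B = 1000, seed = 1L) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  model <- fit_fun(data)
  y <- as.numeric(data[[model$outcome]])
  metrics <- function(m, d) {
    yy <- as.numeric(d[[m$outcome]])
    pp <- ntcp(m, d)
    ll1 <- sum(yy * log(pp) + (1 - yy) * log(1 - pp))
    ll0 <- loglik_null(yy)
    c(auc = auc(yy, pp),
      nagelkerke_r2 = if (ll1 >= ll0) nagelkerke_r2(ll1, ll0, length(yy)) else 0,
      discrimination_slope = discrimination_slope(yy, pp))
  }
  apparent <- metrics(model, data)
  opt <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(apparent)))
  slopes <- numeric(B); intercepts <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(nrow(data), replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      db <- data[idx, , drop = FALSE]
      mb <- tryCatch(fit_fun(db), error = function(e) NULL)
      if (is.null(mb)) { slopes[b] <- NA; next }
      opt[b, ] <- metrics(mb, db) - metrics(mb, data)
      lp <- qlogis(pmin(pmax(ntcp(mb, data), 1e-12), 1 - 1e-12))
      if (stats::sd(lp) > 0) {
        cal <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
        slopes[b] <- stats::coef(cal)[2]
        intercepts[b] <- stats::coef(cal)[1]
      } else { slopes[b] <- NA; intercepts[b] <- NA }
    }
  })
  optimism <- colMeans(opt, na.rm = TRUE)
  mean_slope <- mean(slopes, na.rm = TRUE)
  beta <- model$coefficients
  shrunk <- beta
  shrunk[names(shrunk) != "(Intercept)"] <-
    shrunk[names(shrunk) != "(Intercept)"] * mean_slope
  # refit the intercept with the shrunken slopes held fixed
  X <- as.matrix(data[, model$predictors, drop = FALSE])
  off <- as.vector(X %*% shrunk[model$predictors])
  refit <- suppressWarnings(stats::glm(y ~ 1 + offset(off),
                                       family = stats::binomial()))
  shrunk["(Intercept)"] <- stats::coef(refit)[1]
  model$corrected <- shrunk
  structure(list(model = model, apparent = apparent, optimism = optimism,
                 corrected = apparent - optimism,
                 calibration_slope = mean_slope,
                 calibration_intercept = mean(intercepts, na.rm = TRUE),
                 B = B),
            class = "internal_validation")
}

#' @export
print.internal_validation <- function(x, ...) {
  cat("<internal_validation> B =", x$B,
      " mean calibration slope =", round(x$calibration_slope, 3), "\n")
  print(round(rbind(apparent = x$apparent, optimism = x$optimism,
                    corrected = x$corrected), 4))
  invisible(x)
}

#' @rdname internal_validate
#' @param x an `internal_validation`
#' @param ... unused
#' @export
tidy.internal_validation <- function(x, ...) {
  tibble::tibble(metric = names(x$apparent),
                 apparent = unname(x$apparent),
                 optimism = unname(x$optimism),
                 corrected = unname(x$corrected))
}
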