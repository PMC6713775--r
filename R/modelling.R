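#' Fit a logistic NTCP model
#'
#' Maximum-likelihood logistic regression of a binary complication endpoint on
#' clinical-scale predictors (e.g. baseline status 0/1, mean dose in Gy,
#' surface change in cm^2). Fitting is by iteratively reweighted least squares
#' with a tight convergence tolerance; complete separation is detected and
#' reported as an error naming the offending predictor.
#'
#' @param data data frame containing outcome and predictors
#' @param outcome name of the binary outcome column
#' @param predictors character vector of predictor column names (empty for an
#'   intercept-only model)
#' @return object of class `ntcp_model`: named coefficients, covariance of the
#'   estimates, log-likelihood, null log-likelihood, n, fitted probabilities
#' @export
fit_logistic <- function(data, outcome, predictors = character(0)) {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column `", outcome, "` not found", call. = FALSE)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; logistic model undefined", call. = FALSE)
  if (nrow(data) <= length(predictors) + 1)
    stop("need n > p + 1 observations", call. = FALSE)
  fml <- stats::as.formula(paste(
    outcome, "~", if (length(predictors)) paste(predictors, collapse = " + ") else "1"))
  fit <- suppressWarnings(stats::glm(
    fml, data = data, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(stats::coef(fit)) > 30)) {
    worst <- names(which.max(abs(stats::coef(fit))[-1]))
    stop("complete separation detected (predictor `", worst %||% "intercept",
         "`); coefficients diverge", call. = FALSE)
  }
  ll0 <- loglik_null(y)
  new_ntcp_model(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 log_lik = as.numeric(stats::logLik(fit)), null_log_lik = ll0,
                 n = nrow(data), fitted = unname(mu), outcome = outcome,
                 predictors = predictors)
}

#' Construct an NTCP model from explicit coefficients
#'
#' Used both internally by [fit_logistic()] and to build models from published
#' coefficient tables (no covariance or likelihood needed for prediction).
#'
#' @param coefficients named numeric vector; first element the intercept
#'   (named `(Intercept)` or `intercept`)
#' @param vcov optional covariance matrix of the coefficients
#' @param log_lik,null_log_lik optional log-likelihoods
#' @param n optional sample size
#' @param fitted optional fitted probabilities
#' @param outcome,predictors bookkeeping names
#' @param corrected optional named vector of optimism-corrected coefficients
#' @return `ntcp_model` object
#' @export
new_ntcp_model <- function(coefficients, vcov = NULL, log_lik = NA_real_,
                           null_log_lik = NA_real_, n = NA_integer_,
                           fitted = NULL, outcome = "y",
                           predictors = setdiff(names(coefficients),
                                                c("(Intercept)", "intercept")),
                           corrected = NULL) {
  stopifnot(!is.null(names(coefficients)))
  names(coefficients)[names(coefficients) == "intercept"] <- "(Intercept)"
  structure(list(coefficients = coefficients, vcov = vcov, log_lik = log_lik,
                 null_log_lik = null_log_lik, n = n, fitted = fitted,
                 outcome = outcome, predictors = predictors,
                 corrected = corrected),
            class = "ntcp_model")
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat("<ntcp_model> ", x$outcome, " ~ ",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      "  (n = ", x$n, ", logLik = ", signif(x$log_lik, 6), ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.null(x$corrected)) {
    cat("optimism-corrected:\n")
    print(round(x$corrected, 4))
  }
  invisible(x)
}

#' @rdname fit_logistic
#' @param x an `ntcp_model`
#' @param ... unused
#' @export
tidy.ntcp_model <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, length(x$coefficients))
  est <- x$coefficients
  tibble::tibble(term = names(est), estimate = unname(est), std.error = unname(se),
                 statistic = unname(est / se),
                 p.value = 2 * stats::pnorm(-abs(unname(est / se))))
}

#' @rdname fit_logistic
#' @export
glance.ntcp_model <- function(x, ...) {
  tibble::tibble(logLik = x$log_lik, null_logLik = x$null_log_lik, n = x$n,
                 df = length(x$coefficients))
}

#' Odds ratios with Wald 95% confidence intervals
#'
#' `OR = exp(beta)` per predictor on its natural unit (per Gy, per cm^2, 0/1);
#' intervals are `exp(beta +/- 1.96 se)` where a covariance is available.
#'
#' @param model `ntcp_model`
#' @return tibble `term`, `beta`, `or`, `ci_low`, `ci_high`
#' @export
odds_ratios <- function(model) {
  est <- model$coefficients
  keep <- names(est) != "(Intercept)"
  se <- if (!is.null(model$vcov)) sqrt(diag(model$vcov)) else rep(NA_real_, length(est))
  tibble::tibble(term = names(est)[keep], beta = unname(est[keep]),
                 or = exp(unname(est[keep])),
                 ci_low = exp(unname(est[keep]) - 1.96 * unname(se[keep])),
                 ci_high = exp(unname(est[keep]) + 1.96 * unname(se[keep])))
}

#' Predict complication probability (NTCP)
#'
#' `p = 1 / (1 + exp(-(b0 + sum(b_i x_i))))` on the model's named predictors.
#'
#' @param model `ntcp_model`
#' @param covariates data frame (or named list/vector) providing every
#'   predictor the model names; an error names any that are missing
#' @param use_corrected use the optimism-corrected coefficients if present
#' @return numeric vector of probabilities in (0, 1)
#' @export
ntcp <- function(model, covariates, use_corrected = FALSE) {
  beta <- if (use_corrected) {
    if (is.null(model$corrected)) stop("model has no corrected coefficients", call. = FALSE)
    model$corrected
  } else model$coefficients
  names(beta)[names(beta) == "intercept"] <- "(Intercept)"
  if (!is.data.frame(covariates)) covariates <- as.data.frame(as.list(covariates))
  need <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("missing covariate(s): ", paste(miss, collapse = ", "), call. = FALSE)
  lp <- rep(unname(beta["(Intercept)"]), nrow(covariates))
  for (nm in need) lp <- lp + beta[[nm]] * as.numeric(covariates[[nm]])
  plogis(lp)
}

#' Likelihood-ratio test between nested logistic models
#'
#' @param nested,full `ntcp_model`s fitted to the same rows, with the nested
#'   model's predictors a subset of the full model's
#' @return tibble `statistic`, `df`, `p_value`
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (!all(nested$predictors %in% full$predictors))
    stop("models are not nested: `",
         paste(setdiff(nested$predictors, full$predictors), collapse = ", "),
         "` not in the full model", call. = FALSE)
  if (!identical(nested$n, full$n))
    stop("models were fitted to different numbers of rows", call. = FALSE)
  stat <- max(2 * (full$log_lik - nested$log_lik), 0)
  df <- length(full$predictors) - length(nested$predictors)
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

#' Univariable linear regression (dose vs delta-feature)
#'
#' Ordinary least squares of `y` on `x`, with the coefficient of
#' determination, the slope p-value, and a Shapiro-Wilk residual-normality
#' p-value reported as a diagnostic (not enforced).
#'
#' @param data data frame
#' @param x,y column names of predictor and response
#' @return object of class `delta_linfit` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `shapiro_p`
#' @export
fit_linear <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(xv) == 0) stop("constant predictor `", x, "`", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
  shp <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                  error = function(e) NA_real_)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(xv), shapiro_p = shp, x = x, y = y,
                 data = tibble::tibble(x = xv, y = yv)),
            class = "delta_linfit")
}

#' @export
print.delta_linfit <- function(x, ...) {
  cat("<delta_linfit> ", x$y, " ~ ", x$x, ": slope ", signif(x$slope, 4),
      ", R^2 ", round(x$r_squared, 3), ", p ", signif(x$p_value, 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @rdname fit_linear
#' @param x a `delta_linfit`
#' @param ... unused
#' @export
glance.delta_linfit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value, n = x$n,
                 shapiro_p = x$shapiro_p)
}
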