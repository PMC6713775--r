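#' Variable-selection configuration
#'
#' @param correlation_threshold pairwise |Pearson r| above which only the
#'   feature with the stronger univariable association is kept (default 0.80)
#' @param forward_alpha likelihood-ratio-test entry p-value for forward
#'   selection (default 0.01)
#' @param n_bootstrap number of bootstrap resamples over which the whole
#'   procedure is repeated (default 1000)
#' @param rng_seed integer seed
#' @return object of class `selection_config`
#' @export
selection_config <- function(correlation_threshold = 0.80, forward_alpha = 0.01,
                             n_bootstrap = 1000L, rng_seed = 1L) {
  stopifnot(correlation_threshold > 0, correlation_threshold <= 1,
            forward_alpha > 0, forward_alpha < 1, n_bootstrap >= 1)
  structure(list(correlation_threshold = correlation_threshold,
                 forward_alpha = forward_alpha,
                 n_bootstrap = as.integer(n_bootstrap),
                 rng_seed = as.integer(rng_seed)),
            class = "selection_config")
}

#' Column-wise z-score normalisation
#'
#' Centres each column on the across-patient mean and divides by the sample
#' standard deviation. Zero-variance columns cannot be standardised and are
#' dropped with a warning.
#'
#' @param x numeric matrix or data frame (>= 2 rows)
#' @return numeric matrix with `center`/`scale` attributes
#' @export
zscore_normalise <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to normalise", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop))
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  x <- x[, !drop, drop = FALSE]
  scale(x)
}

# logistic fit machinery shared by the selection module --------------------

# returns log-likelihood, coefficients and separation flag for y ~ X
loglik_logistic <- function(X, y) {
  X <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = stats::glm.control(maxit = 100)))
  mu <- fit$fitted.values
  sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(fit$coefficients) > 30)
  list(ll = -fit$deviance / 2, coef = fit$coefficients, separation = sep)
}

loglik_null <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) return(-Inf)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

#' Correlation prefilter with univariable tie-breaking
#'
#' Among each pair of features whose |Pearson correlation| exceeds the
#' threshold, only the one with the larger univariable log-likelihood
#' improvement against the binary endpoint is kept. Pairs are resolved
#' greedily in descending |r|; a pair whose loser was already removed is
#' skipped, making the result deterministic for a given column order.
#'
#' @param x normalised numeric matrix (patients x features)
#' @param y binary outcome (0/1)
#' @param threshold |r| threshold (default 0.80)
#' @return character vector of kept feature names (input order preserved)
#' @export
correlation_prefilter <- function(x, y, threshold = 0.80) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (ncol(x) < 2) return(nm)
  ll0 <- loglik_null(y)
  uni <- vapply(seq_len(ncol(x)), function(j)
    loglik_logistic(x[, j, drop = FALSE], y)$ll - ll0, numeric(1))
  r <- stats::cor(x)
  pairs <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(abs(r[pairs]), decreasing = TRUE)
    removed <- rep(FALSE, ncol(x))
    for (q in ord) {
      a <- pairs[q, 1]; b <- pairs[q, 2]
      if (removed[a] || removed[b]) next
      loser <- if (uni[a] >= uni[b]) b else a
      removed[loser] <- TRUE
    }
    nm <- nm[!removed]
  }
  nm
}

#' Stepwise forward selection by likelihood-ratio test
#'
#' Starting from the intercept-only model, repeatedly adds the candidate with
#' the smallest LRT p-value against the current model, stopping when the best
#' p-value is not below `alpha`. Candidates whose trial fit shows complete
#' separation are skipped at that step (they remain candidates later). Ties
#' are broken by the larger absolute univariable coefficient, then by name.
#'
#' @param x normalised numeric matrix
#' @param y binary outcome (0/1)
#' @param alpha LRT entry threshold (default 0.01)
#' @return character vector of selected features, in entry order (possibly
#'   empty), with attribute `log_lik` of the final model
#' @export
forward_select <- function(x, y, alpha = 0.01) {
  x <- as.matrix(x)
  nm <- colnames(x)
  selected <- character(0)
  ll_cur <- loglik_null(y)
  uni_coef <- vapply(seq_len(ncol(x)), function(j) {
    f <- loglik_logistic(x[, j, drop = FALSE], y)
    unname(f$coef[2])
  }, numeric(1))
  names(uni_coef) <- nm
  repeat {
    cand <- setdiff(nm, selected)
    if (!length(cand)) break
    res <- lapply(cand, function(cn) {
      f <- loglik_logistic(x[, c(selected, cn), drop = FALSE], y)
      list(name = cn, ll = f$ll, sep = f$separation)
    })
    ok <- Filter(function(r) !r$sep && is.finite(r$ll), res)
    if (!length(ok)) break
    stat <- vapply(ok, function(r) max(2 * (r$ll - ll_cur), 0), numeric(1))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    names_ok <- vapply(ok, `[[`, character(1), "name")
    best_p <- min(p)
    if (best_p >= alpha) break
    tied <- which(p <= best_p + 1e-12)
    if (length(tied) > 1) {
      tb <- abs(uni_coef[names_ok[tied]])
      tied <- tied[order(-tb, names_ok[tied])]
    }
    pick <- tied[1]
    selected <- c(selected, names_ok[pick])
    ll_cur <- ok[[pick]]$ll
  }
  attr(selected, "log_lik") <- ll_cur
  selected
}

#' Bootstrap stability of the full selection procedure
#'
#' Repeats normalisation, correlation prefilter and forward selection on
#' bootstrap resamples (rows drawn with replacement; resamples with a single
#' outcome class are redrawn) and counts how often each feature is selected.
#'
#' @param x numeric matrix or wide tibble of features (raw scale; each
#'   resample is re-normalised internally)
#' @param y binary outcome (0/1)
#' @param config [selection_config()]
#' @return tibble `feature`, `count`, `n_bootstrap`, sorted by count;
#'   attribute `n_redraws` records how many degenerate resamples were redrawn
#' @export
bootstrap_selection <- function(x, y, config = selection_config()) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2)
    stop("outcome has a single class in the full data", call. = FALSE)
  counts <- stats::setNames(rep(0L, ncol(x)), colnames(x))
  redraws <- 0L
  with_seed(config$rng_seed, {
    for (b in seq_len(config$n_bootstrap)) {
      repeat {
        idx <- sample.int(nrow(x), replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        redraws <- redraws + 1L
      }
      xb <- suppressWarnings(zscore_normalise(x[idx, , drop = FALSE]))
      yb <- y[idx]
      kept <- correlation_prefilter(xb, yb, config$correlation_threshold)
      sel <- forward_select(xb[, kept, drop = FALSE], yb, config$forward_alpha)
      counts[sel] <- counts[sel] + 1L
    }
  })
  out <- tibble::tibble(feature = names(counts), count = as.integer(counts),
                        n_bootstrap = config$n_bootstrap)
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$feature)
  attr(out, "n_redraws") <- redraws
  out
}

#' Univariable logistic scan of every feature
#'
#' One-predictor logistic fit per feature, reporting the coefficient, its
#' Wald and likelihood-ratio p-values, and a separation flag (separated fits
#' get an infinite-coefficient marker rather than a numeric estimate).
#'
#' @param x normalised numeric matrix
#' @param y binary outcome (0/1)
#' @return tibble `feature`, `beta`, `se`, `p_wald`, `p_lrt`, `separation`
#' @export
univariable_scan <- function(x, y) {
  x <- as.matrix(x)
  ll0 <- loglik_null(y)
  rows <- lapply(colnames(x), function(cn) {
    X <- cbind(1, x[, cn])
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                           control = stats::glm.control(maxit = 100)))
    mu <- fit$fitted.values
    sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(fit$coefficients) > 30)
    if (sep) {
      return(tibble::tibble(feature = cn, beta = Inf * sign(fit$coefficients[2]),
                            se = NA_real_, p_wald = NA_real_, p_lrt = NA_real_,
                            separation = TRUE))
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(W))
    se <- sqrt(diag(solve(XtWX)))[2]
    b <- fit$coefficients[2]
    ll1 <- -fit$deviance / 2
    tibble::tibble(feature = cn, beta = unname(b), se = unname(se),
                   p_wald = 2 * stats::pnorm(-abs(b / se)),
                   p_lrt = stats::pchisq(max(2 * (ll1 - ll0), 0), 1,
                                         lower.tail = FALSE),
                   separation = FALSE)
  })
  dplyr::bind_rows(rows)
}
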