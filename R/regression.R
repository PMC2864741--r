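#' log10(x+1) transform and its inverse
#'
#' The standard transform for right-skewed, zero-inflated density data
#' (population, GDP): zero maps to zero and zeros can be retained.
#'
#' @param values non-negative numeric vector.
#' @return transformed vector.
#' @export
log10p1 <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("log10p1 requires non-negative values", call. = FALSE)
  }
  log10(values + 1)
}

#' @rdname log10p1
#' @export
inv_log10p1 <- function(values) 10^values - 1

#' Ordinary least-squares linear fit
#'
#' Thin wrapper over [stats::lm()] that reports the quantities the analyses
#' use: intercept, slope, r-squared, and Gaussian AIC (which counts the
#' residual variance as a parameter, so k = 3 for a simple regression).
#'
#' @param x predictor vector.
#' @param y response vector.
#' @return an object of class `linear_fit`.
#' @export
linear_fit <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("singular design: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r2 = 1 - rss / sum((y - mean(y))^2),
         AIC = stats::AIC(fit), n = n, k = 3,
         residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit))),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g + %.4g x, r2 = %.3f, AIC = %.1f (n = %d)\n",
              x$intercept, x$slope, x$r2, x$AIC, x$n))
  invisible(x)
}

#' Breakpoint (two-segment) regression
#'
#' Fits the continuous piecewise-linear mean
#' `y = a + b*min(x, c) + d*max(x - c, 0)` — four mean parameters — by
#' exhaustive grid search over the breakpoint `c` (by default, the
#' predictor's 5th-95th percentile range at step 0.005), solving the
#' remaining linear least-squares problem at each candidate and keeping the
#' `c` with minimal residual sum of squares (ties go to the smallest `c`).
#' AIC counts 5 parameters (4 mean + residual variance).
#'
#' @param x predictor vector.
#' @param y response vector.
#' @param c_grid candidate breakpoints, or "auto".
#' @return an object of class `breakpoint_fit` with `a`, `b`, `c`, `d`, `r2`,
#'   `AIC`, `n`, `residuals`, `fitted`.
#' @export
breakpoint_fit <- function(x, y, c_grid = "auto") {
  n <- length(x)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (identical(c_grid, "auto")) {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    c_grid <- seq(q[1], q[2], by = 0.005)
  }
  c_grid <- sort(c_grid)
  best <- NULL
  best_rss <- Inf
  tried <- 0L
  for (cc in c_grid) {
    if (sum(x < cc) < 3 || sum(x > cc) < 3) next
    tried <- tried + 1L
    X <- cbind(1, pmin(x, cc), pmax(x - cc, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) {   # strict improvement: ties keep smallest c
      best_rss <- rss
      best <- list(c = cc, coef = fit$coefficients, fit = fit)
    }
  }
  if (is.null(best)) {
    stop("no identifiable breakpoint: fewer than 3 points on one side of every candidate",
         call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  k <- 5
  aic <- n * (log(2 * pi * best_rss / n) + 1) + 2 * k
  structure(
    list(a = unname(best$coef[1]), b = unname(best$coef[2]), c = best$c,
         d = unname(best$coef[3]), r2 = 1 - best_rss / tss, AIC = aic, n = n,
         k = k, residuals = unname(best$fit$residuals),
         fitted = unname(best$fit$fitted.values), n_candidates = tried),
    class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> a = %.4g, b = %.4g, c = %.4g, d = %.4g; r2 = %.3f, AIC = %.1f (n = %d)\n",
    x$a, x$b, x$c, x$d, x$r2, x$AIC, x$n))
  invisible(x)
}

#' AIC model comparison
#'
#' Ranks fits of the same response by AIC and reports the difference to the
#' best model.
#'
#' @param fits named list of fit objects carrying `AIC` and `n`.
#' @return data.frame sorted by AIC with columns `model`, `AIC`, `dAIC`, `k`.
#' @export
compare_aic <- function(fits) {
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("fits were not computed on the same response (n differs)", call. = FALSE)
  }
  out <- data.frame(model = names(fits),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    k = vapply(fits, function(f) if (is.null(f$k)) NA_real_ else f$k,
                               numeric(1)))
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood logistic regression
#'
#' Wraps [stats::glm()] (binomial family, IRLS) and reports the coefficient
#' table with Wald tests, the model chi-square against the intercept-only
#' model, and classification accuracy at probability 0.5. Perfect separation
#' is flagged, not fatal.
#'
#' @param X data.frame or matrix of predictors.
#' @param y binary response (0/1, logical, or two-level factor).
#' @return an object of class `logistic_fit` with `coefficients` (matrix:
#'   estimate, se, z, p), `chisq`, `chisq_df`, `chisq_p`, `accuracy`, `n`,
#'   `AIC`, `separation`.
#' @export
logistic_fit <- function(X, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) != 2 || !all(y %in% c(0, 1))) {
    stop("y must be binary with both classes present", call. = FALSE)
  }
  df <- as.data.frame(X)
  df$.y <- y
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) warning("possible perfect separation; coefficients unstable")
  sm <- summary(fit)$coefficients
  colnames(sm) <- c("estimate", "se", "z", "p")
  chisq <- unname(fit$null.deviance - fit$deviance)
  chisq_df <- unname(fit$df.null - fit$df.residual)
  pred <- as.numeric(stats::fitted(fit) >= 0.5)
  structure(
    list(coefficients = sm, chisq = chisq, chisq_df = chisq_df,
         chisq_p = stats::pchisq(chisq, chisq_df, lower.tail = FALSE),
         accuracy = mean(pred == y), n = length(y), AIC = stats::AIC(fit),
         k = length(stats::coef(fit)), separation = separation,
         glm = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, chi2 = %.1f (df %d, p = %.3g), accuracy = %.2f\n",
              x$n, x$chisq, x$chisq_df, x$chisq_p, x$accuracy))
  print(round(x$coefficients, 4))
  invisible(x)
}

# evaluate a fit's mean function on raw predictor values
fit_mean_function <- function(fit, x) {
  if (inherits(fit, "linear_fit")) {
    fit$intercept + fit$slope * x
  } else if (inherits(fit, "breakpoint_fit")) {
    segmented_mean(x, fit$a, fit$b, fit$c, fit$d)
  } else {
    stop("predict_surface supports linear_fit and breakpoint_fit objects",
         call. = FALSE)
  }
}

#' Extrapolate a population/GDP model over a suitability surface
#'
#' Evaluates the fitted mean (trained on the log10(x+1) scale) at every cell
#' of the suitability grid, back-transforms (`10^y - 1`), and floors at zero.
#'
#' @param fit a `linear_fit` or `breakpoint_fit` trained on log10(x+1) data.
#' @param suitability a `suitability_surface` or `landsuit_grid` on the same
#'   flavor/scale the fit was trained on.
#' @return a `landsuit_grid` of predicted densities (nodata propagated).
#' @export
predict_surface <- function(fit, suitability) {
  g <- if (inherits(suitability, "suitability_surface")) suitability$grid else suitability
  stopifnot(is_grid(g))
  out <- g
  out$values <- pmax(10^fit_mean_function(fit, g$values) - 1, 0)
  out
}

#' Residual map on the natural scale
#'
#' `observed - predicted`, cell by cell, on the natural (people per km^2)
#' scale. Because the model is fitted on log-transformed data, positive
#' residuals run larger than negative ones; this asymmetry is expected and
#' carries no functional meaning.
#'
#' @param observed,predicted congruent `landsuit_grid`s.
#' @return a `landsuit_grid` of residuals.
#' @export
residual_map <- function(observed, predicted) {
  stopifnot(is_grid(observed), is_grid(predicted))
  stop_if_incongruent(observed, predicted, "residual inputs")
  out <- observed
  out$values <- observed$values - predicted$values
  out
}
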