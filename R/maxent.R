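#' @section Maxent-lite model:
#' The fitted distribution is the Gibbs distribution over background cells,
#' `p_i = exp(lambda . f_i) / Z`, that minimizes the regularized negative
#' mean log-probability of the presence records. Feature classes are linear
#' and quadratic transforms of each continuous covariate (rescaled to `[0,1]`
#' on the background) and one indicator per observed categorical class.
#' @name maxent-lite
#' @keywords internal
NULL

# drop bookkeeping columns, keep covariates only
covtab_covariates <- function(tab) {
  drop <- intersect(c("lon", "lat", "label", "in_extent", "on_nodata"), names(tab))
  tab[setdiff(names(tab), drop)]
}

#' Build a feature expansion from a background table
#'
#' Records, per continuous covariate, the background min/max used to rescale
#' to `[0,1]` (values outside the background range are clamped at prediction
#' time), and per categorical covariate the set of observed classes. The
#' expansion is reproducible from these stored statistics.
#'
#' @param background covariate data.frame (numeric columns are continuous,
#'   factor columns categorical; `lon`/`lat` are ignored).
#' @return an object of class `feature_expansion`.
#' @export
build_feature_expansion <- function(background) {
  tab <- covtab_covariates(background)
  cont <- names(tab)[vapply(tab, is.numeric, logical(1))]
  cat <- names(tab)[vapply(tab, is.factor, logical(1))]
  if (length(cat) > 1) stop("at most one categorical covariate is supported", call. = FALSE)
  rng <- lapply(tab[cont], function(x) {
    r <- range(x)
    if (r[1] == r[2]) r[2] <- r[1] + 1  # constant layer: features all 0
    r
  })
  classes <- if (length(cat)) levels(droplevels(tab[[cat]])) else character()
  means <- vapply(tab[cont], mean, numeric(1))
  mode_class <- if (length(cat)) {
    names(which.max(table(droplevels(tab[[cat]]))))
  } else NULL
  structure(list(continuous = cont, ranges = rng, categorical = cat,
                 classes = classes, bg_means = means, bg_mode = mode_class),
            class = "feature_expansion")
}

#' Expand covariates into model features
#'
#' @param expansion a `feature_expansion`.
#' @param tab covariate data.frame.
#' @return numeric matrix of features in `[0,1]`.
#' @export
expand_features <- function(expansion, tab) {
  tab <- covtab_covariates(tab)
  cols <- list()
  for (nm in expansion$continuous) {
    x <- tab[[nm]]
    if (is.null(x)) stop("covariate missing from table: ", nm, call. = FALSE)
    if (any(!is.finite(x))) stop("non-finite values in covariate ", nm, call. = FALSE)
    r <- expansion$ranges[[nm]]
    z <- pmin(pmax((x - r[1]) / (r[2] - r[1]), 0), 1)
    cols[[paste0(nm, "_lin")]] <- z
    cols[[paste0(nm, "_quad")]] <- z^2
  }
  if (length(expansion$categorical)) {
    f <- tab[[expansion$categorical]]
    if (is.null(f)) stop("categorical covariate missing from table", call. = FALSE)
    obs <- as.character(f)
    unseen <- setdiff(unique(obs), expansion$classes)
    if (length(unseen)) {
      warning("unseen categorical class(es) at prediction: ",
              paste(unseen, collapse = ", "), "; indicators set to zero")
    }
    for (cl in expansion$classes) {
      cols[[paste0(expansion$categorical, "_", cl)]] <- as.numeric(obs == cl)
    }
  }
  do.call(cbind, cols)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Fit a maximum-entropy (Gibbs) suitability model
#'
#' Minimizes the convex objective
#' `-mean(lambda . f(presence)) + log sum(exp(lambda . f(background)))
#'  + sum_j beta_j |lambda_j|`
#' by proximal gradient descent with backtracking line search. The per-feature
#' penalty is `beta_j = beta * max(s_j, 0.05) / sqrt(m)` where `s_j` is the
#' presence-sample standard deviation of feature `j` and `m` the number of
#' presences, so `beta` acts as a single regularization multiplier
#' (default 1) in the way users of maximum-entropy niche models expect.
#'
#' @param presences covariate data.frame of presence records (>= 5 rows).
#' @param background covariate data.frame of background cells.
#' @param beta regularization multiplier (>= 0).
#' @param max_iter maximum proximal-gradient iterations.
#' @param tol stop when the objective improves by less than this.
#' @param lambda_init optional initial weights (default all zero).
#' @return an object of class `maxent_model` with elements `lambda`,
#'   `beta_j`, `logZ`, `H` (entropy of the fitted distribution over the
#'   background), `bg_raw` (Gibbs probabilities of the background cells,
#'   summing to 1), `expansion`, `objective`, `converged`.
#' @export
fit_maxent <- function(presences, background, beta = 1, max_iter = 1000,
                       tol = 1e-8, lambda_init = NULL) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  m <- nrow(presences)
  if (m < 5) stop("need at least 5 presence records", call. = FALSE)
  expansion <- build_feature_expansion(background)
  Fb <- expand_features(expansion, background)
  Fp <- expand_features(expansion, presences)
  if (any(!is.finite(Fb)) || any(!is.finite(Fp))) {
    stop("non-finite feature values", call. = FALSE)
  }
  J <- ncol(Fb)
  s_j <- apply(Fp, 2, stats::sd)
  beta_j <- beta * pmax(s_j, 0.05) / sqrt(m)
  fbar <- colMeans(Fp)

  g_val <- function(lam) -sum(fbar * lam) + logsumexp(Fb %*% lam)
  lam <- if (is.null(lambda_init)) numeric(J) else as.numeric(lambda_init)
  gv <- g_val(lam)
  obj <- gv + sum(beta_j * abs(lam))
  t_step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- Fb %*% lam
    p <- exp(eta - logsumexp(eta))
    grad <- -fbar + as.numeric(crossprod(Fb, p))
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- lam - t_step * grad
      cand <- sign(cand) * pmax(abs(cand) - t_step * beta_j, 0)
      dlt <- cand - lam
      gc_ <- g_val(cand)
      if (gc_ <= gv + sum(grad * dlt) + sum(dlt^2) / (2 * t_step) + 1e-12) {
        accepted <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!accepted) break
    new_obj <- gc_ + sum(beta_j * abs(cand))
    improvement <- obj - new_obj
    lam <- cand
    gv <- gc_
    obj <- new_obj
    t_step <- min(t_step * 1.3, 1e8)
    if (improvement >= 0 && improvement < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("maxent fit did not converge in ", max_iter, " iterations")
  }
  eta <- as.numeric(Fb %*% lam)
  logZ <- logsumexp(eta)
  p <- exp(eta - logZ)
  H <- -sum(p * log(p))
  structure(
    list(lambda = stats::setNames(as.numeric(lam), colnames(Fb)),
         beta = beta, beta_j = beta_j, logZ = logZ, H = H, bg_raw = p,
         expansion = expansion, objective = obj, converged = converged,
         n_presences = m, n_background = nrow(Fb)),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d feature(s), %d presences, %d background cells\n",
              length(x$lambda), x$n_presences, x$n_background))
  cat(sprintf("  objective %.6f, entropy %.4f, converged: %s\n",
              x$objective, x$H, x$converged))
  nz <- sum(x$lambda != 0)
  cat(sprintf("  non-zero weights: %d\n", nz))
  invisible(x)
}

#' Suitability surfaces
#'
#' A grid of model output in one of three flavors: `raw` (Gibbs
#' probabilities, summing to 1 over the training background), `cumulative`
#' (for each cell, the summed raw value of all background cells with raw at
#' or below that cell's, on `[0,1]`), or `logistic` (prevalence-scaled
#' probability of occurrence in (0,1)).
#'
#' @param grid a `landsuit_grid` of output values.
#' @param flavor one of "raw", "cumulative", "logistic".
#' @param bg_raw raw values at the training background cells.
#' @param H entropy of the fitted distribution.
#' @export
suitability_surface <- function(grid, flavor = c("raw", "cumulative", "logistic"),
                                bg_raw = NULL, H = NULL) {
  flavor <- match.arg(flavor)
  structure(list(grid = grid, flavor = flavor, bg_raw = bg_raw, H = H),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("<suitability_surface> flavor: %s\n", x$flavor))
  print(x$grid)
  invisible(x)
}

check_flavor <- function(surface, expected) {
  if (!inherits(surface, "suitability_surface")) {
    stop("expected a suitability_surface", call. = FALSE)
  }
  if (surface$flavor != expected) {
    stop(sprintf("surface flavor must be '%s', got '%s'", expected, surface$flavor),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict the raw Gibbs surface over a covariate stack
#'
#' Evaluates `exp(lambda . f(cell) - log Z)` cell by cell, with `Z` the
#' normalizer from the training background, and propagates nodata.
#'
#' @param model a `maxent_model`.
#' @param stack a `covariate_stack` with the covariates of the expansion.
#' @return a `suitability_surface` of flavor "raw".
#' @export
predict_raw <- function(model, stack) {
  stopifnot(inherits(model, "maxent_model"), is_covariate_stack(stack))
  ref <- stack_reference(stack)
  cells <- stack_valid_cells(stack)
  tab <- stack_table(stack, cells)
  Fm <- expand_features(model$expansion, tab)
  raw <- exp(as.numeric(Fm %*% model$lambda) - model$logZ)
  vals <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  vals[cells] <- raw
  g <- ref
  g$values <- vals
  suitability_surface(g, "raw", bg_raw = model$bg_raw, H = model$H)
}

#' Convert a raw surface to cumulative output
#'
#' The cumulative value of a cell is the sum of the raw values of all
#' training-background cells whose raw value is at or below the cell's own
#' (ties inclusive), on a `[0,1]` scale. It is a monotone transform of raw,
#' used for thresholding.
#'
#' @param raw a `suitability_surface` of flavor "raw".
#' @return a `suitability_surface` of flavor "cumulative".
#' @export
to_cumulative <- function(raw) {
  check_flavor(raw, "raw")
  if (is.null(raw$bg_raw)) stop("surface carries no background raw values", call. = FALSE)
  sorted <- sort(raw$bg_raw)
  cs <- cumsum(sorted)
  total <- cs[length(cs)]
  # inclusive ties: index of the last background value <= cell value
  idx <- findInterval(raw$grid$values, sorted)
  cum <- ifelse(idx == 0, 0, cs[pmax(idx, 1)]) / total
  g <- raw$grid
  g$values <- matrix(cum, g$n_rows, g$n_cols)
  g$values[is.na(raw$grid$values)] <- NA_real_
  suitability_surface(g, "cumulative", bg_raw = raw$bg_raw, H = raw$H)
}

#' Convert a raw surface to logistic output
#'
#' `logistic = c*r / (1 + c*r)` with `r` the raw value and `c = exp(H)`, so a
#' cell of typical (entropy-level) raw value maps to 0.5: the conventional
#' prevalence-scaled "probability of occurrence".
#'
#' @param raw a `suitability_surface` of flavor "raw".
#' @param H entropy override; default is the value stored on the surface.
#' @return a `suitability_surface` of flavor "logistic".
#' @export
to_logistic <- function(raw, H = NULL) {
  check_flavor(raw, "raw")
  if (is.null(H)) H <- raw$H
  if (is.null(H)) stop("no entropy available for the logistic transform", call. = FALSE)
  er <- exp(H) * raw$grid$values
  g <- raw$grid
  g$values <- er / (1 + er)
  suitability_surface(g, "logistic", bg_raw = raw$bg_raw, H = H)
}

#' Threshold a cumulative surface into a binary presence/absence grid
#'
#' @param cumulative a `suitability_surface` of flavor "cumulative".
#' @param t threshold in `[0,1]`; cells with cumulative >= t become 1.
#' @return a binary `landsuit_grid` (nodata propagated).
#' @export
apply_threshold <- function(cumulative, t) {
  check_flavor(cumulative, "cumulative")
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop("threshold t must lie in [0, 1]", call. = FALSE)
  }
  g <- cumulative$grid
  g$values <- (g$values >= t) * 1
  g
}

#' Rank AUC of presence scores against background scores
#'
#' The probability that a random presence outscores a random background
#' point, ties counted half (the normalized Mann-Whitney U statistic).
#'
#' @param pos scores of presences.
#' @param neg scores of background points.
#' @return AUC in `[0,1]`.
#' @export
auc_score <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (!np || !nn) stop("need scores in both groups", call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated AUC of a maxent model
#'
#' Splits the presences into `k` folds (the background is shared), fits on
#' k-1 folds and scores the held-out presences against the full background by
#' the model's linear predictor.
#'
#' @param presences covariate data.frame of presences.
#' @param background covariate data.frame of background cells.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param beta regularization multiplier.
#' @param ... passed to [fit_maxent()].
#' @return an object of class `model_evaluation` with `fold_auc`, `mean_auc`.
#' @export
crossval_auc <- function(presences, background, k = 10, seed = 1L, beta = 1, ...) {
  m <- nrow(presences)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (m < k) stop("fewer presences than folds", call. = FALSE)
  folds <- local_seed(seed, sample(rep(seq_len(k), length.out = m)))
  fold_auc <- numeric(k)
  for (i in seq_len(k)) {
    train <- presences[folds != i, , drop = FALSE]
    test <- presences[folds == i, , drop = FALSE]
    if (!nrow(test)) stop("fold ", i, " has zero presences", call. = FALSE)
    fit <- fit_maxent(train, background, beta = beta, ...)
    sc_test <- expand_features(fit$expansion, test) %*% fit$lambda
    sc_bg <- expand_features(fit$expansion, background) %*% fit$lambda
    fold_auc[i] <- auc_score(as.numeric(sc_test), as.numeric(sc_bg))
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc), k = k),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %d-fold cross-validation, mean AUC %.3f\n",
              x$k, x$mean_auc))
  invisible(x)
}

#' Permutation variable importance
#'
#' For each covariate, the mean drop in held-out AUC when that covariate's
#' values are permuted across the evaluation cells (its derived features move
#' with it), averaged over `n_runs` resampled train/test splits and
#' renormalized to sum to 1.
#'
#' @param presences covariate data.frame of presences.
#' @param background covariate data.frame of background cells.
#' @param n_runs number of runs with distinct sub-seeds.
#' @param seed integer seed.
#' @param beta regularization multiplier.
#' @param holdout fraction of presences held out per run.
#' @param ... passed to [fit_maxent()].
#' @return named numeric vector of contributions (non-negative, summing to 1
#'   unless no variable matters, in which case all zero).
#' @export
variable_contributions <- function(presences, background, n_runs = 10, seed = 1L,
                                   beta = 1, holdout = 0.3, ...) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  vars <- names(covtab_covariates(background))
  m <- nrow(presences)
  drops <- matrix(0, n_runs, length(vars), dimnames = list(NULL, vars))
  for (run in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, paste0("contrib", run))
    idx <- local_seed(run_seed, sample(m, max(2, round(holdout * m))))
    train <- presences[-idx, , drop = FALSE]
    test <- presences[idx, , drop = FALSE]
    fit <- fit_maxent(train, background, beta = beta, ...)
    eval_tab <- rbind(covtab_covariates(test)[vars],
                      covtab_covariates(background)[vars])
    np <- nrow(test)
    score <- function(tab) {
      sc <- as.numeric(expand_features(fit$expansion, tab) %*% fit$lambda)
      auc_score(sc[seq_len(np)], sc[-seq_len(np)])
    }
    base <- score(eval_tab)
    perm <- local_seed(derive_seed(run_seed, "perm"), {
      vapply(vars, function(v) {
        tab <- eval_tab
        tab[[v]] <- tab[[v]][sample(nrow(tab))]
        score(tab)
      }, numeric(1))
    })
    drops[run, ] <- pmax(base - perm, 0)
  }
  mean_drop <- colMeans(drops)
  tot <- sum(mean_drop)
  if (tot <= 0) {
    warning("no variable affected held-out AUC; contributions undefined")
    return(stats::setNames(rep(0, length(vars)), vars))
  }
  mean_drop / tot
}

#' Partial response curve of one covariate
#'
#' Varies the covariate over its background range in `n_steps` while the
#' other continuous covariates sit at their background means and the
#' categorical at its modal class; reports the logistic-flavor output.
#'
#' @param model a `maxent_model`.
#' @param variable covariate name.
#' @param n_steps number of evaluation points.
#' @return data.frame with columns `value`, `suitability`.
#' @export
response_curve <- function(model, variable, n_steps = 100) {
  exp_ <- model$expansion
  if (!variable %in% c(exp_$continuous, exp_$categorical)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (variable %in% exp_$continuous) {
    r <- exp_$ranges[[variable]]
    values <- seq(r[1], r[2], length.out = n_steps)
  } else {
    values <- exp_$classes
    n_steps <- length(values)
  }
  tab <- as.data.frame(lapply(exp_$bg_means, rep, n_steps))
  names(tab) <- exp_$continuous
  if (length(exp_$categorical)) {
    tab[[exp_$categorical]] <- factor(rep(exp_$bg_mode, n_steps),
                                      levels = exp_$classes)
  }
  if (variable %in% exp_$continuous) {
    tab[[variable]] <- values
  } else {
    tab[[variable]] <- factor(values, levels = exp_$classes)
  }
  raw <- exp(as.numeric(expand_features(exp_, tab) %*% model$lambda) - model$logZ)
  er <- exp(model$H) * raw
  data.frame(value = if (is.numeric(values)) values else as.character(values),
             suitability = er / (1 + er))
}
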