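test_that("two-state worlds reproduce the closed-form maximum-entropy solution", {
  # N0 background cells with feature 0, N1 with feature 1; a fraction q of
  # presences in state 1. The unregularized Gibbs solution satisfies
  # E[f] = q, i.e. P(state 1) = q, exp(lambda) = q*N0 / ((1-q)*N1).
  bg <- data.frame(x = c(rep(0, 60), rep(1, 40)))
  pres <- data.frame(x = rep(c(1, 0), c(30, 10)))
  fit <- fit_maxent(pres, bg, beta = 0, max_iter = 5000, tol = 1e-12)
  p1 <- sum(fit$bg_raw[bg$x == 1])
  expect_lt(abs(p1 - 0.75), 1e-6)
  lam_expect <- log(0.75 * 60 / (0.25 * 40))
  expect_lt(abs(sum(fit$lambda) - lam_expect), 1e-4)

  # degenerate corner: all presences in one state; mass goes to 1
  fit1 <- fit_maxent(data.frame(x = rep(1, 30)), bg, beta = 0,
                     max_iter = 5000, tol = 1e-12)
  expect_lt(abs(sum(fit1$bg_raw[bg$x == 1]) - 1), 1e-4)
})

test_that("raw probabilities always sum to one over the background", {
  w <- small_world()
  d <- world_design(w, 60, 1500, seed = 3)
  fit <- fit_maxent(d$presences, d$background, beta = 1)
  expect_lt(abs(sum(fit$bg_raw) - 1), 1e-8)
  # exhaustive background: predicted raw sums to 1 over the whole grid
  dall <- list(background = stack_table(w$stack, stack_valid_cells(w$stack)))
  fit2 <- fit_maxent(d$presences, dall$background, beta = 1)
  raw <- predict_raw(fit2, w$stack)
  expect_lt(abs(sum(raw$grid$values, na.rm = TRUE) - 1), 1e-8)
})

test_that("prediction agrees with direct evaluation of the Gibbs formula", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 40, 500, seed = 4)
  fit <- fit_maxent(d$presences, d$background)
  raw <- predict_raw(fit, w$stack)
  cells <- stack_valid_cells(w$stack)
  Fm <- expand_features(fit$expansion, stack_table(w$stack, cells))
  brute <- exp(as.numeric(Fm %*% fit$lambda) - fit$logZ)
  expect_equal(unname(raw$grid$values[cells]), brute, tolerance = 1e-12)
})

test_that("presences drawn uniformly carry no signal", {
  w <- small_world(n = 50, seed = 13)
  flat <- new_grid(matrix(1, 50, 50), cell_size = w$true_suitability$cell_size)
  pres <- sample_presences(flat, 500, seed = 21)
  pc <- extract_at_points(w$stack, pres)
  bg <- build_background(w$stack, 2000, seed = 22)
  fit <- fit_maxent(pc, bg, beta = 0)
  sc_p <- expand_features(fit$expansion, pc) %*% fit$lambda
  sc_b <- expand_features(fit$expansion, bg) %*% fit$lambda
  expect_lt(abs(auc_score(as.numeric(sc_p), as.numeric(sc_b)) - 0.5), 0.05)
})

test_that("the convex objective is initialization-independent", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 40, 500, seed = 4)
  tol <- 1e-10
  f1 <- fit_maxent(d$presences, d$background, tol = tol)
  set.seed(77)
  init <- rnorm(length(f1$lambda), sd = 0.5)
  f2 <- fit_maxent(d$presences, d$background, tol = tol, lambda_init = init)
  expect_lt(abs(f1$objective - f2$objective), 10 * tol + 1e-9)
})

test_that("a zero-weight model predicts the uniform distribution", {
  w <- small_world(n = 20, seed = 9)
  bg <- stack_table(w$stack, stack_valid_cells(w$stack))
  expansion <- build_feature_expansion(bg)
  J <- ncol(expand_features(expansion, bg[1:2, ]))
  fit <- structure(
    list(lambda = stats::setNames(numeric(J), NULL), logZ = log(nrow(bg)),
         H = log(nrow(bg)), bg_raw = rep(1 / nrow(bg), nrow(bg)),
         expansion = expansion),
    class = "maxent_model")
  raw <- predict_raw(fit, w$stack)
  expect_equal(unique(round(c(raw$grid$values), 15)), 1 / nrow(bg))
  # uniform raw: cumulative is 1 everywhere (ties inclusive), logistic 0.5
  cum <- to_cumulative(raw)
  expect_equal(unique(c(cum$grid$values)), 1)
  logi <- to_logistic(raw)
  expect_equal(unique(round(c(logi$grid$values), 12)), 0.5)
})

test_that("cumulative output is a monotone rank-preserving transform", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 40, 500, seed = 4)
  fit <- fit_maxent(d$presences, d$background)
  raw <- predict_raw(fit, w$stack)
  cum <- to_cumulative(raw)
  r <- c(raw$grid$values); cc <- c(cum$grid$values)
  expect_true(all(cc >= 0 & cc <= 1))
  # the maximal raw cell reaches cumulative 1 (background spans the stack)
  expect_equal(max(cc), 1)
  o <- order(r)
  expect_true(all(diff(cc[o]) >= -1e-12))
  # identical raw values share one cumulative value
  expect_equal(length(unique(cc[r == max(r)])), 1)
  expect_error(to_cumulative(cum), "flavor")
})

test_that("logistic output is a strictly increasing map into (0,1)", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 40, 500, seed = 4)
  fit <- fit_maxent(d$presences, d$background)
  raw <- predict_raw(fit, w$stack)
  logi <- to_logistic(raw)
  v <- c(logi$grid$values)
  expect_true(all(v > 0 & v < 1))
  o <- order(c(raw$grid$values))
  expect_true(all(diff(v[o]) >= 0))
  expect_error(to_logistic(logi), "flavor")
})

test_that("rank AUC matches exhaustive pair counting and handles ties", {
  expect_equal(auc_score(rep(1, 10), rep(1, 15)), 0.5)
  expect_equal(auc_score(2:4, c(0, 1)), 1)
  set.seed(55)
  pos <- sample(1:10, 12, replace = TRUE) + 0.5 * rbinom(12, 1, 0.5)
  neg <- sample(1:10, 18, replace = TRUE)
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_score(pos, neg), brute)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(12, 18)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_score(pos, neg), ref)
})

test_that("cross-validation reports per-fold AUC and rejects bad folds", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 50, 500, seed = 4)
  ev <- crossval_auc(d$presences, d$background, k = 5, seed = 8)
  expect_length(ev$fold_auc, 5)
  expect_equal(ev$mean_auc, mean(ev$fold_auc))
  expect_true(all(ev$fold_auc >= 0 & ev$fold_auc <= 1))
  expect_error(crossval_auc(d$presences, d$background, k = 1), "k must be")
  expect_error(crossval_auc(d$presences[1:3, ], d$background, k = 5), "fewer")
})

test_that("permutation importance finds the driving covariate and ignores noise", {
  # niche driven by temperature only; precipitation independent noise
  cfg <- landscape_config(n_rows = 50, n_cols = 50, seed = 17)
  niche <- true_niche(intercept = -2, linear = c(temperature = 4),
                      quadratic = c(temperature = -3))
  w <- synth_landscape(cfg, niche = niche)
  d <- world_design(w, 100, 1000, seed = 5)
  contrib <- variable_contributions(d$presences, d$background, n_runs = 5, seed = 3)
  expect_equal(sum(contrib), 1)
  expect_equal(names(which.max(contrib)), "temperature")
  expect_lt(contrib[["precipitation"]], 0.25)
})

test_that("a single-covariate model gets the whole contribution", {
  bg <- data.frame(x = rnorm(400))
  pres <- data.frame(x = rnorm(60, mean = 1))
  contrib <- variable_contributions(pres, bg, n_runs = 3, seed = 2)
  expect_equal(unname(contrib), 1)
})

test_that("response curves reflect the fitted feature shapes", {
  set.seed(42)
  bg <- data.frame(x = runif(500), z = runif(500))
  # presences concentrated at high x: monotone increasing response in x
  pres <- data.frame(x = runif(100, 0.6, 1), z = runif(100))
  fit <- fit_maxent(pres, bg, beta = 0.5)
  rc <- response_curve(fit, "x", n_steps = 50)
  expect_equal(nrow(rc), 50)
  expect_equal(range(rc$value), range(bg$x))
  expect_gt(stats::cor(rc$value, rc$suitability, method = "spearman"), 0.95)
  # unimodal niche: interior maximum at the analytic vertex of the quadratic
  pres2 <- data.frame(x = runif(150, 0.35, 0.65), z = runif(150))
  fit2 <- fit_maxent(pres2, bg, beta = 0.5)
  rc2 <- response_curve(fit2, "x", n_steps = 201)
  r <- fit2$expansion$ranges$x
  lam <- fit2$lambda[c("x_lin", "x_quad")]
  vertex <- r[1] + (-lam[1] / (2 * lam[2])) * (r[2] - r[1])
  expect_lt(lam[2], 0)
  expect_lt(abs(rc2$value[which.max(rc2$suitability)] - vertex), 0.02)
  expect_error(response_curve(fit, "nope"), "unknown")
})

test_that("thresholding a cumulative surface is inclusive and validated", {
  w <- small_world(n = 30, seed = 11)
  d <- world_design(w, 40, 500, seed = 4)
  cum <- to_cumulative(predict_raw(fit_maxent(d$presences, d$background), w$stack))
  b0 <- apply_threshold(cum, 0)
  expect_true(all(b0$values == 1))
  b <- apply_threshold(cum, 0.18)
  v <- c(cum$grid$values)
  expect_equal(c(b$values), as.numeric(v >= 0.18))
  b1 <- apply_threshold(cum, 1)
  expect_equal(sum(b1$values), sum(v == max(v)))
  expect_error(apply_threshold(cum, 1.5), "\\[0, 1\\]")
  expect_error(apply_threshold(suitability_surface(w$true_suitability, "raw"), 0.5),
               "flavor")
})

test_that("unseen categorical classes fall back to baseline with a warning", {
  bg <- data.frame(x = rnorm(200), soil = factor(sample(1:3, 200, replace = TRUE)))
  pres <- data.frame(x = rnorm(30, 1), soil = factor(sample(1:3, 30, replace = TRUE)))
  fit <- fit_maxent(pres, bg)
  new_tab <- data.frame(x = c(0, 0), soil = factor(c(1, 9), levels = c(1, 9)))
  expect_warning(Fm <- expand_features(fit$expansion, new_tab), "unseen")
  expect_equal(sum(Fm[2, grep("soil", colnames(Fm))]), 0)
})
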