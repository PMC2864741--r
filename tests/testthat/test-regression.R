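test_that("the log10(x+1) transform and its inverse round trip", {
  expect_equal(log10p1(0), 0)
  expect_equal(log10p1(99), 2)
  set.seed(2)
  x <- 10^runif(100, -3, 6)
  expect_equal(inv_log10p1(log10p1(x)), x, tolerance = 1e-10)
  expect_error(log10p1(-1), "non-negative")
})

test_that("linear fits agree with the closed-form normal equations", {
  x <- seq(0, 1, length.out = 20)
  exact <- linear_fit(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r2, 1)
  set.seed(6)
  xr <- rnorm(200); yr <- 0.7 * xr + rnorm(200)
  fit <- linear_fit(xr, yr)
  slope_cf <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  expect_equal(fit$slope, slope_cf)
  expect_equal(fit$intercept, mean(yr) - slope_cf * mean(xr))
  # independence: r2 near zero
  expect_lt(linear_fit(xr, rnorm(200))$r2, 0.05)
  expect_error(linear_fit(rep(1, 10), rnorm(10)), "singular")
})

test_that("noise-free two-segment data identify all four parameters", {
  set.seed(11)
  x <- runif(300)
  y <- segmented_mean(x, 0.2, 6, 0.3, 0.5)
  fit <- breakpoint_fit(x, y, c_grid = seq(0.05, 0.95, by = 0.005))
  expect_equal(fit$c, 0.3)
  expect_equal(fit$a, 0.2, tolerance = 1e-8)
  expect_equal(fit$b, 6, tolerance = 1e-8)
  expect_equal(fit$d, 0.5, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("breakpoint never loses to the nested linear model, and AIC protects parsimony", {
  set.seed(31)
  linear_wins <- 0
  for (i in 1:50) {
    x <- runif(120)
    y <- 1 + 2 * x + rnorm(120, sd = 0.5)
    lf <- linear_fit(x, y)
    bf <- breakpoint_fit(x, y)
    expect_gte(bf$r2, lf$r2)
    cmp <- compare_aic(list(linear = lf, breakpoint = bf))
    linear_wins <- linear_wins + (cmp$model[1] == "linear")
  }
  expect_gt(linear_wins / 50, 0.6)
})

test_that("breakpoint recovery works through the population generator", {
  sg <- new_grid(matrix(runif(2000), 40, 50))
  pop <- synth_population(sg, population_params(0.2, 6, 0.3, 0.5, 0.4), seed = 77)
  fit <- breakpoint_fit(c(sg$values), log10p1(c(pop$values)))
  expect_gt(fit$c, 0.25)
  expect_lt(fit$c, 0.35)
  expect_error(breakpoint_fit(rep(0.5, 50), rnorm(50), c_grid = 0.5),
               "identifiable")
})

test_that("AIC comparison checks its inputs and is order-invariant", {
  set.seed(4)
  x <- runif(100); y <- x + rnorm(100)
  lf <- linear_fit(x, y); bf <- breakpoint_fit(x, y)
  one <- compare_aic(list(only = lf))
  expect_equal(one$dAIC, 0)
  c1 <- compare_aic(list(linear = lf, breakpoint = bf))
  c2 <- compare_aic(list(breakpoint = bf, linear = lf))
  expect_equal(c1$model, c2$model)
  expect_equal(c1$dAIC, c2$dAIC)
  short <- linear_fit(x[1:50], y[1:50])
  expect_error(compare_aic(list(a = lf, b = short)), "same response")
})

test_that("logistic fits match the closed-form log odds ratio on a 2x2 table", {
  x <- rep(c(0, 1), c(40, 40))
  y <- c(rep(c(0, 1), c(30, 10)), rep(c(0, 1), c(12, 28)))
  fit <- logistic_fit(data.frame(x = x), y)
  or <- (28 / 12) / (10 / 30)
  expect_equal(unname(fit$coefficients["x", "estimate"]), log(or), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)", "estimate"]), log(10 / 30),
               tolerance = 1e-6)
})

test_that("logistic fits agree with a brute-force likelihood search", {
  set.seed(19)
  x <- rnorm(20)
  y <- rbinom(20, 1, stats::plogis(0.5 + 1.2 * x))
  fit <- logistic_fit(data.frame(x = x), y)
  nll <- function(b) -sum(stats::dbinom(y, 1, stats::plogis(b[1] + b[2] * x), log = TRUE))
  grid_b0 <- seq(-4, 4, by = 0.001)
  b1_hat <- unname(fit$coefficients["x", "estimate"])
  prof <- vapply(grid_b0, function(b0) nll(c(b0, b1_hat)), numeric(1))
  expect_lt(abs(grid_b0[which.min(prof)] -
                unname(fit$coefficients["(Intercept)", "estimate"])), 1e-3)
  opt <- stats::optim(c(0, 0), nll)$par
  expect_lt(abs(opt[2] - b1_hat), 1e-3)
})

test_that("null logistic models show small chi-square and majority-rate accuracy", {
  set.seed(23)
  y <- rbinom(300, 1, 0.3)
  fit <- logistic_fit(data.frame(x = rnorm(300)), y)
  expect_lt(fit$chisq, stats::qchisq(0.99, 1))
  expect_equal(fit$accuracy, max(mean(y), 1 - mean(y)), tolerance = 0.05)
  # perfect separation is flagged, not fatal
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(sep <- logistic_fit(data.frame(x = xs), ys), "separation")
  expect_true(sep$separation)
  expect_error(logistic_fit(data.frame(x = rnorm(10)), rep(1, 10)), "both classes")
})

test_that("model surfaces back-transform and floor correctly", {
  fit <- structure(list(a = 0.2, b = 6, c = 0.3, d = 0.5),
                   class = "breakpoint_fit")
  const <- predict_surface(fit, new_grid(matrix(0.4, 3, 3)))
  expect_equal(length(unique(c(const$values))), 1)
  knot <- predict_surface(fit, new_grid(matrix(0.3, 1, 1)))
  expect_equal(knot$values[1, 1], 10^(0.2 + 6 * 0.3) - 1)
  # brute-force agreement over a random grid
  set.seed(3)
  sgrid <- new_grid(matrix(runif(60), 6, 10))
  pred <- predict_surface(fit, sgrid)
  brute <- pmax(10^(0.2 + 6 * pmin(sgrid$values, 0.3) +
                      0.5 * pmax(sgrid$values - 0.3, 0)) - 1, 0)
  expect_equal(pred$values, brute)
  # deeply negative mean: floored at zero
  neg <- structure(list(intercept = -10, slope = 0), class = "linear_fit")
  expect_true(all(predict_surface(neg, sgrid)$values == 0))
})

test_that("residual maps subtract on the natural scale and skew positive", {
  a <- new_grid(matrix(5, 2, 2)); b <- new_grid(matrix(3, 2, 2))
  expect_equal(residual_map(a, a)$values, matrix(0, 2, 2))
  expect_equal(residual_map(a, b)$values, matrix(2, 2, 2))
  # unbiased generator: residuals centered on the log scale, skewed natural
  sg <- new_grid(matrix(runif(2000), 40, 50))
  pars <- population_params(0.2, 6, 0.3, 0.5, 0.4)
  pop <- synth_population(sg, pars, seed = 13)
  mean_grid <- sg
  mean_grid$values <- segmented_mean(sg$values, 0.2, 6, 0.3, 0.5)
  log_resid <- log10p1(pop$values) - mean_grid$values
  expect_lt(abs(mean(log_resid)), 0.05)
  pred <- sg
  pred$values <- pmax(10^mean_grid$values - 1, 0)
  nat <- residual_map(pop, pred)$values
  expect_gt(mean((nat - mean(nat))^3) / stats::sd(nat)^3, 0.5)
})
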