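test_that("Moran's I matches its null expectation, known patterns, and ape", {
  set.seed(3)
  co <- cbind(runif(100), runif(100))
  w <- dist_band_weights(co, 0.2)
  # i.i.d. values: near -1/(n-1)
  vals <- rnorm(100)
  i0 <- morans_i(vals, w)
  expect_lt(abs(i0 - (-1 / 99)), 0.1)
  # smooth gradient: strongly positive
  expect_gt(morans_i(co[, 1] + co[, 2], w), 0.5)
  # checkerboard on rook weights: negative
  m <- outer(1:6, 1:6, function(i, j) (-1)^(i + j))
  expect_lt(morans_i_lattice(m, "rook"), -0.9)
  # constant input: flagged as undefined
  expect_warning(ic <- morans_i(rep(1, 100), w), "constant")
  expect_true(is.na(ic))
  skip_if_not_installed("ape")
  # ape row-standardizes its weight matrix; feed ours the same normalization
  w_std <- w$w / pmax(rowSums(w$w), 1)
  ref <- ape::Moran.I(vals, w$w, scaled = FALSE)$observed
  expect_equal(morans_i(vals, w_std), ref, tolerance = 1e-10)
})

test_that("lattice Moran's I equals the dense-matrix version", {
  set.seed(8)
  m <- matrix(rnorm(49), 7, 7)
  centers <- expand.grid(row = 1:7, col = 1:7)
  d <- as.matrix(stats::dist(centers))
  wq <- (d > 0 & d < 1.5) * 1   # queen: all 8 neighbors within sqrt(2)
  expect_equal(morans_i_lattice(m, "queen"),
               morans_i(c(m), spatial_weights(wq, centers)), tolerance = 1e-12)
})

test_that("correlograms decay with distance for autocorrelated fields", {
  set.seed(21)
  g <- gaussian_random_field(60, 60, 10, seed = 31)
  cells <- sample(3600, 300)
  rc <- arrayInd(cells, c(60, 60))
  co <- cbind(rc[, 2], rc[, 1])
  cg <- correlogram(g$values[cells], co, n_classes = 10)
  expect_equal(which.max(cg$moran), 1)
  expect_gt(cg$moran[1], 0.5)
  expect_lt(mean(cg$moran[8:10]), cg$moran[1] / 2)
  # white noise: every class near the null expectation
  cgw <- correlogram(rnorm(300), co, n_classes = 10)
  expect_true(all(abs(cgw$moran - (-1 / 299)) < 0.15))
  # bookkeeping: pair counts sum to n(n-1)/2
  cg2 <- correlogram(rnorm(300), co, n_classes = 2)
  expect_equal(nrow(cg2), 2)
  expect_equal(sum(cg2$n_pairs), 300 * 299 / 2)
})

test_that("the corrected test reduces to the ordinary one for white noise", {
  set.seed(5)
  dfs <- replicate(20, {
    co <- cbind(runif(200, 0, 60), runif(200, 0, 60))
    dutilleul_correlation(rnorm(200), rnorm(200), co)$df_adj
  })
  expect_lt(abs(mean(dfs) - 198) / 198, 0.10)
  expect_true(all(dfs <= 198 + 1e-6))
})

test_that("autocorrelation shrinks the adjusted degrees of freedom", {
  shrunk <- 0
  for (i in 1:20) {
    g1 <- gaussian_random_field(60, 60, 10, seed = 400 + i)
    g2 <- gaussian_random_field(60, 60, 10, seed = 4400 + i)
    set.seed(i)
    cells <- sample(3600, 200)
    rc <- arrayInd(cells, c(60, 60))
    co <- cbind(rc[, 2], rc[, 1])
    d <- dutilleul_correlation(g1$values[cells], g2$values[cells], co)
    expect_lte(d$df_adj, 198 + 1e-6)
    shrunk <- shrunk + (d$df_adj < 150)
  }
  expect_gte(shrunk, 19)
})

test_that("perfect correlation and degenerate input behave as contracts say", {
  set.seed(9)
  co <- cbind(runif(50), runif(50))
  x <- rnorm(50)
  d <- dutilleul_correlation(x, x, co)
  expect_equal(d$r, 1)
  expect_error(dutilleul_correlation(rep(1, 50), x, co), "constant")
  expect_error(dutilleul_correlation(x[1:5], x[1:5], co[1:5, ]), "at least 10")
})

test_that("MEM eigenvectors are orthogonal, centered, and eigenvalue-ordered", {
  set.seed(14)
  co <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  b <- mem_basis(co)
  ip <- crossprod(b$vectors)
  expect_lt(max(abs(ip - diag(ncol(b$vectors)))), 1e-8)
  expect_lt(max(abs(colSums(b$vectors))), 1e-8)
  expect_true(all(diff(b$values) <= 1e-12))
  expect_true(all(b$values > 0))
  # the leading eigenvector carries the strongest spatial signal
  expect_equal(unname(which.max(b$moran)), 1L)
  expect_error(mem_basis(matrix(1, 12, 2)), "coincident")
})

test_that("MEM on a regular lattice matches a brute-force eigendecomposition", {
  co <- as.matrix(expand.grid(x = 1:5, y = 1:5))
  b <- mem_basis(co, truncation = 1)
  # independent dense construction: double-centered binary connectivity
  d <- as.matrix(stats::dist(co))
  w <- (d > 0 & d <= 1) * 1
  n <- nrow(w)
  B <- diag(n) - matrix(1 / n, n, n)
  eig <- eigen(B %*% w %*% B, symmetric = TRUE)
  pos <- eig$values > 1e-8
  expect_equal(b$values, eig$values[pos], tolerance = 1e-8)
  # eigenvectors match up to sign within eigenvalue multiplicity
  for (k in seq_along(b$values)) {
    same <- abs(eig$values - b$values[k]) < 1e-8
    proj <- eig$vectors[, same, drop = FALSE]
    resid <- b$vectors[, k] - proj %*% crossprod(proj, b$vectors[, k])
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("forward selection finds a planted eigenvector and stops on white noise", {
  set.seed(26)
  co <- cbind(runif(80, 0, 10), runif(80, 0, 10))
  b <- mem_basis(co)
  # white residuals: nothing selected (at a typical draw of the noise)
  set.seed(123)
  sel0 <- select_eigenvectors(b, rnorm(80), max_k = 5, seed = 2, n_perm = 499)
  expect_length(sel0$selected, 0)
  # residuals dominated by vector 3: it is picked first
  e <- 3 * b$vectors[, 3] + rnorm(80, sd = 0.3)
  sel3 <- select_eigenvectors(b, e, max_k = 5, seed = 2)
  expect_equal(sel3$selected[1], 3L)
  expect_lte(length(sel3$selected), 5)
  # each addition reduces the absolute residual autocorrelation
  expect_true(all(diff(sel3$moran_path) <= 1e-9))
})
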