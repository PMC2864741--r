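#' Spatial weights over sample locations
#'
#' A symmetric non-negative weight matrix with zero diagonal plus the
#' coordinates it refers to. `dist_band_weights()` builds the common binary
#' distance-band connectivity: 1 for pairs closer than `d_max`, else 0.
#' Distances here and throughout are planar Euclidean on the coordinates.
#'
#' @param w symmetric non-negative matrix with zero diagonal.
#' @param coords two-column matrix or data.frame of point coordinates.
#' @return an object of class `spatial_weights`.
#' @export
spatial_weights <- function(w, coords) {
  w <- as.matrix(w)
  coords <- as.matrix(coords[, 1:2])
  if (nrow(w) != ncol(w) || nrow(w) != nrow(coords)) {
    stop("weight matrix and coordinates are inconsistent", call. = FALSE)
  }
  if (any(w < 0) || any(abs(diag(w)) > 0) || any(abs(w - t(w)) > 1e-12)) {
    stop("weights must be non-negative, symmetric, with zero diagonal", call. = FALSE)
  }
  structure(list(w = w, coords = coords), class = "spatial_weights")
}

#' @rdname spatial_weights
#' @param d_max inclusion distance for the band.
#' @export
dist_band_weights <- function(coords, d_max) {
  coords <- as.matrix(coords[, 1:2])
  d <- as.matrix(stats::dist(coords))
  w <- (d > 0 & d <= d_max) * 1
  spatial_weights(w, coords)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)` with `z` the centered
#' values and `S0` the total weight. Under spatial independence its
#' expectation is `-1/(n-1)`. Constant input has no defined autocorrelation
#' and returns `NA` with a warning.
#'
#' @param values numeric vector.
#' @param w a `spatial_weights` object (or bare matrix).
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, w) {
  if (inherits(w, "spatial_weights")) w <- w$w
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  s0 <- sum(w)
  if (s0 <= 0) stop("weights are all zero", call. = FALSE)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("Moran's I undefined for constant values")
    return(NA_real_)
  }
  (n / s0) * as.numeric(t(z) %*% w %*% z) / denom
}

#' Moran's I on a full lattice (queen or rook contiguity)
#'
#' Efficient computation for gridded data via neighbor shifts, avoiding the
#' dense n-squared weight matrix.
#'
#' @param grid a `landsuit_grid` or numeric matrix (no nodata allowed).
#' @param style "queen" (8 neighbors) or "rook" (4 neighbors).
#' @return Moran's I (scalar).
#' @export
morans_i_lattice <- function(grid, style = c("queen", "rook")) {
  style <- match.arg(style)
  m <- if (is_grid(grid)) grid$values else as.matrix(grid)
  if (any(is.na(m))) stop("lattice Moran's I requires a complete grid", call. = FALSE)
  z <- m - mean(m)
  nr <- nrow(z); nc <- ncol(z)
  shifts <- list(c(0, 1), c(1, 0))
  if (style == "queen") shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  num <- 0; s0 <- 0
  for (sh in shifts) {
    dr <- sh[1]; dc <- sh[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- z[r1, c1, drop = FALSE]
    b <- z[r1 + dr, c1 + dc, drop = FALSE]
    num <- num + 2 * sum(a * b)    # each shifted pair counted both ways
    s0 <- s0 + 2 * length(a)
  }
  n <- length(z)
  (n / s0) * num / sum(z^2)
}

#' Distance-class correlogram
#'
#' Splits all point pairs into `n_classes` equal-frequency distance classes
#' and computes Moran's I within each class (binary in-class weights).
#' Classes that end up with fewer than `min_pairs` pairs are merged into
#' their nearer neighbor (logged as a message). The per-class estimates are
#' the piecewise-constant spatial autocorrelation used by
#' [dutilleul_correlation()].
#'
#' @param values numeric vector.
#' @param coords two-column coordinates.
#' @param n_classes number of distance classes (>= 2).
#' @param min_pairs minimum pairs a class must hold.
#' @return data.frame with columns `class`, `d_max`, `n_pairs`, `moran`.
#' @export
correlogram <- function(values, coords, n_classes = 10, min_pairs = 8) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  coords <- as.matrix(coords[, 1:2])
  n <- length(values)
  d <- stats::dist(coords)
  breaks <- distance_class_breaks(d, n_classes)
  cls_pair <- cut_distance(as.numeric(d), breaks)
  tab <- tabulate(cls_pair, nbins = length(breaks))
  while (any(tab < min_pairs) && length(breaks) > 2) {
    k <- which(tab < min_pairs)[1]
    message("merging distance class ", k, " (", tab[k], " pairs)")
    breaks <- breaks[-max(k - 1, 1)]
    cls_pair <- cut_distance(as.numeric(d), breaks)
    tab <- tabulate(cls_pair, nbins = length(breaks))
  }
  z <- values - mean(values)
  denom <- sum(z^2)
  dm <- as.matrix(d)
  clsm <- matrix(cut_distance(as.numeric(dm), breaks), n, n)
  diag(clsm) <- 0L
  zz <- tcrossprod(z)
  out <- data.frame(class = seq_along(breaks), d_max = breaks,
                    n_pairs = tab, moran = NA_real_)
  for (k in seq_along(breaks)) {
    sel <- clsm == k
    s0 <- sum(sel)
    out$moran[k] <- if (s0 > 0) (n / s0) * sum(zz[sel]) / denom else NA_real_
  }
  out
}

# equal-frequency class upper bounds from the pairwise distance distribution
distance_class_breaks <- function(d, n_classes) {
  q <- stats::quantile(d, probs = seq_len(n_classes) / n_classes, names = FALSE)
  unique(q)
}

# class index of each distance: smallest k with d <= breaks[k]
cut_distance <- function(d, breaks) {
  idx <- findInterval(d, breaks, left.open = TRUE) + 1L
  idx[idx > length(breaks)] <- length(breaks)  # guard FP edge at the max
  idx
}

#' Correlation test corrected for spatial autocorrelation (Dutilleul)
#'
#' Computes the ordinary Pearson correlation, then replaces the sample size
#' in its test by an effective sample size that discounts the spatial
#' autocorrelation of both variables. Spatial covariance matrices are
#' estimated piecewise-constant over equal-frequency distance classes from
#' each variable's correlogram; with `B` the centering projector, the
#' effective sample size is
#' `M = 1 + [tr(B Sx B Sy) / (tr(B Sx) tr(B Sy))]^-1`, the adjusted degrees
#' of freedom `df_adj = M - 2`, and `F_adj = df_adj * r^2 / (1 - r^2)` is
#' referred to an F distribution on `(1, df_adj)`. `M` is capped at `n`, so
#' `df_adj <= n - 2`; for spatially independent data `M` approaches `n` and
#' the test reduces to the ordinary one.
#'
#' @param x,y numeric vectors (length >= 10).
#' @param coords two-column coordinates of the sample locations.
#' @param n_classes distance classes for the correlogram.
#' @return an object of class `spatial_correlation` with `r`, `r2`, `F_adj`,
#'   `df_adj`, `p`, `n`, `n_eff`.
#' @export
dutilleul_correlation <- function(x, y, coords, n_classes = 10) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  coords <- as.matrix(coords[, 1:2])
  d <- stats::dist(coords)
  breaks <- distance_class_breaks(d, n_classes)
  dm <- as.matrix(d)
  clsm <- matrix(cut_distance(as.numeric(dm), breaks), n, n)
  diag(clsm) <- 0L
  Cx <- centered_spatial_cov(x, clsm, length(breaks))
  Cy <- centered_spatial_cov(y, clsm, length(breaks))
  trx <- sum(diag(Cx))
  try_ <- sum(diag(Cy))
  num <- sum(Cx * Cy)      # tr((B Sx B)(B Sy B)) for symmetric matrices
  var_r <- num / (trx * try_)
  M <- if (is.finite(var_r) && var_r > 0) 1 + 1 / var_r else n
  M <- min(max(M, 3), n)
  df_adj <- M - 2
  r <- stats::cor(x, y)
  F_adj <- df_adj * r^2 / (1 - r^2)
  p <- stats::pf(F_adj, 1, df_adj, lower.tail = FALSE)
  structure(list(r = r, r2 = r^2, F_adj = F_adj, df_adj = df_adj, p = p,
                 n = n, n_eff = M),
            class = "spatial_correlation")
}

# B S B for the piecewise-constant spatial covariance estimate of v
centered_spatial_cov <- function(v, clsm, n_classes) {
  z <- v - mean(v)
  s2 <- mean(z^2)
  n <- length(v)
  # per-class autocorrelation (Moran with binary in-class weights), clamped
  zz <- tcrossprod(z)
  rho <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    sel <- clsm == k
    s0 <- sum(sel)
    rho[k] <- if (s0 > 0) (n / s0) * sum(zz[sel]) / sum(z^2) else 0
  }
  rho <- pmin(pmax(rho, -1), 1)
  S <- matrix(0, n, n)
  pos <- clsm > 0
  S[pos] <- s2 * rho[clsm[pos]]
  diag(S) <- s2
  rm_ <- rowMeans(S)
  S - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(S)
}

#' @export
print.spatial_correlation <- function(x, ...) {
  cat(sprintf(
    "<spatial_correlation> r = %.3f (r2 = %.3f), F_adj = %.2f, df_adj = %.1f, p = %.4g (n = %d)\n",
    x$r, x$r2, x$F_adj, x$df_adj, x$p, x$n))
  invisible(x)
}

# Prim's minimum spanning tree on a dense distance matrix; returns edge lengths
mst_edge_lengths <- function(dm) {
  n <- nrow(dm)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- dm[1, ]
  edges <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    best[in_tree] <- Inf
    j <- which.min(best)
    edges[k] <- best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, dm[j, ])
  }
  edges
}

#' Moran eigenvector basis for spatial filtering
#'
#' Builds a binary distance-band connectivity matrix (the default truncation
#' is the longest minimum-spanning-tree edge, the smallest distance keeping
#' the graph connected), double-centers it, and eigendecomposes. The
#' eigenvectors with positive eigenvalues — mutually orthogonal and
#' orthogonal to the constant — describe spatial patterns at decreasing
#' scales and serve as spatial covariates in regressions.
#'
#' @param coords two-column coordinates (>= 10 distinct locations).
#' @param truncation connectivity distance, or "auto".
#' @return an object of class `mem_basis` with `vectors` (columns), `values`
#'   (non-increasing positive eigenvalues), `moran` (Moran's I of each vector
#'   on the same connectivity), `truncation`, `weights`.
#' @export
mem_basis <- function(coords, truncation = "auto") {
  coords <- as.matrix(coords[, 1:2])
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 locations", call. = FALSE)
  dm <- as.matrix(stats::dist(coords))
  if (max(dm) == 0) stop("all points are coincident", call. = FALSE)
  if (identical(truncation, "auto")) {
    truncation <- max(mst_edge_lengths(dm))
  }
  w <- (dm > 0 & dm <= truncation) * 1
  cw <- sweep(w, 1, rowMeans(w))
  cw <- sweep(cw, 2, colMeans(cw))
  eig <- eigen(cw, symmetric = TRUE)
  keep <- eig$values > 1e-8 * max(abs(eig$values))
  vectors <- eig$vectors[, keep, drop = FALSE]
  colnames(vectors) <- paste0("MEM", seq_len(ncol(vectors)))
  sw <- spatial_weights(w, coords)
  moran <- apply(vectors, 2, morans_i, w = sw)
  structure(list(vectors = vectors, values = eig$values[keep], moran = moran,
                 truncation = truncation, weights = sw),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf("<mem_basis> %d eigenvector(s), truncation %.4g\n",
              ncol(x$vectors), x$truncation))
  invisible(x)
}

# two-sided permutation test of Moran's I
moran_perm_p <- function(values, w, n_perm = 199, seed = 1L) {
  obs <- morans_i(values, w)
  perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) morans_i(sample(values), w), numeric(1))
  })
  (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
}

#' Forward selection of spatial eigenvectors
#'
#' Greedily adds the eigenvector whose inclusion most reduces the absolute
#' Moran's I of the regression residuals, stopping when the residual
#' autocorrelation is no longer significant (permutation test) or `max_k`
#' vectors are selected.
#'
#' @param basis a [mem_basis()].
#' @param residuals residual vector at the sample locations.
#' @param max_k maximum number of vectors to select.
#' @param alpha significance level of the residual-autocorrelation stop rule.
#' @param n_perm permutations for the test.
#' @param seed integer seed.
#' @return list with `selected` (column indices, possibly empty), `moran_path`
#'   (|Moran's I| after each addition, starting with none), `residuals`
#'   (final residuals).
#' @export
select_eigenvectors <- function(basis, residuals, max_k = ncol(basis$vectors),
                                alpha = 0.05, n_perm = 199, seed = 1L) {
  stopifnot(inherits(basis, "mem_basis"))
  if (max_k > ncol(basis$vectors)) stop("max_k exceeds basis size", call. = FALSE)
  w <- basis$weights
  e0 <- residuals
  selected <- integer()
  path <- abs(morans_i(e0, w))
  cur_resid <- e0
  for (step in seq_len(max_k)) {
    p <- moran_perm_p(cur_resid, w, n_perm = n_perm,
                      seed = derive_seed(seed, paste0("sel", step)))
    if (p >= alpha) break
    remaining <- setdiff(seq_len(ncol(basis$vectors)), selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(j) {
      X <- cbind(1, basis$vectors[, c(selected, j), drop = FALSE])
      abs(morans_i(stats::lm.fit(X, e0)$residuals, w))
    }, numeric(1))
    jbest <- remaining[which.min(trial)]
    selected <- c(selected, jbest)
    X <- cbind(1, basis$vectors[, selected, drop = FALSE])
    cur_resid <- stats::lm.fit(X, e0)$residuals
    path <- c(path, abs(morans_i(cur_resid, w)))
  }
  list(selected = selected, moran_path = path, residuals = cur_resid)
}
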