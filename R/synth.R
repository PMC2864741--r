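#' Gaussian random field on a lattice
#'
#' Simulates a spatially autocorrelated field by convolving white noise with a
#' Gaussian kernel of bandwidth `range_param` (in cell units). The kernel is
#' L2-normalized so every cell is exactly standard normal marginally; the
#' autocorrelation between two cells decays as a Gaussian in their separation,
#' with scale `range_param`. `range_param = 0` gives independent cells.
#' The noise field is padded by three bandwidths so there are no edge or
#' wrap-around artifacts.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param range_param autocorrelation range in cell units; must be >= 0.
#' @param seed integer seed.
#' @param x_ll,y_ll,cell_size georeferencing of the returned grid.
#' @return a `landsuit_grid` with zero-mean, unit-variance values.
#' @export
gaussian_random_field <- function(n_rows, n_cols, range_param, seed = 1L,
                                  x_ll = 0, y_ll = 0, cell_size = 1) {
  if (!is.numeric(range_param) || length(range_param) != 1L || range_param < 0) {
    stop("range_param must be a single non-negative number", call. = FALSE)
  }
  vals <- local_seed(seed, {
    if (range_param == 0) {
      matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    } else {
      half <- ceiling(3 * range_param)
      k <- stats::dnorm(seq(-half, half), sd = range_param)
      k <- k / sqrt(sum(k^2))
      w <- matrix(stats::rnorm((n_rows + 2 * half) * (n_cols + 2 * half)),
                  n_rows + 2 * half, n_cols + 2 * half)
      kr <- kernel_band_matrix(n_rows, k)
      kc <- kernel_band_matrix(n_cols, k)
      kr %*% w %*% t(kc)
    }
  })
  new_grid(vals, x_ll = x_ll, y_ll = y_ll, cell_size = cell_size)
}

# n x (n + len(k) - 1) banded convolution matrix; row i holds k at offset i
kernel_band_matrix <- function(n, k) {
  m <- matrix(0, n, n + length(k) - 1L)
  for (i in seq_len(n)) m[i, i:(i + length(k) - 1L)] <- k
  m
}

#' Landscape configuration
#'
#' Describes the synthetic world: lattice geometry, the continuous covariate
#' fields (each with its own autocorrelation range, mean and sd), and the
#' number of spatially coherent soil classes.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param cell_size cell side length in degrees.
#' @param seed integer master seed for the landscape.
#' @param continuous_fields data.frame with columns `name`, `range`, `mean`,
#'   `sd` — one row per continuous covariate.
#' @param n_soil_classes number of soil classes (>= 2).
#' @param soil_range autocorrelation range of the auxiliary field whose
#'   quantiles define the soil patches.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100, cell_size = 0.05,
                             seed = 1L,
                             continuous_fields = data.frame(
                               name = c("temperature", "precipitation"),
                               range = c(10, 15),
                               mean = c(0, 0),
                               sd = c(1, 1)),
                             n_soil_classes = 4,
                             soil_range = 8) {
  stopifnot(all(c("name", "range", "mean", "sd") %in% names(continuous_fields)))
  if (any(continuous_fields$range < 0)) {
    stop("autocorrelation ranges must be >= 0", call. = FALSE)
  }
  if (n_soil_classes < 2) stop("n_soil_classes must be >= 2", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         seed = as.integer(seed), continuous_fields = continuous_fields,
         n_soil_classes = as.integer(n_soil_classes), soil_range = soil_range),
    class = "landscape_config")
}

#' True niche (ground-truth suitability function)
#'
#' Defines the data-generating suitability: a logistic function of linear and
#' quadratic terms in the continuous covariates plus one offset per soil
#' class, so `s* = plogis(intercept + sum(b1*x + b2*x^2) + soil_offset)` lies
#' strictly in (0, 1).
#'
#' @param intercept scalar intercept.
#' @param linear named vector of linear coefficients (names = covariates).
#' @param quadratic named vector of quadratic coefficients.
#' @param soil_offsets numeric vector, one offset per soil class (code order).
#' @return an object of class `true_niche`.
#' @export
true_niche <- function(intercept = 0, linear = numeric(), quadratic = numeric(),
                       soil_offsets = numeric()) {
  structure(list(intercept = intercept, linear = linear, quadratic = quadratic,
                 soil_offsets = soil_offsets),
            class = "true_niche")
}

# The package's default "strong niche": unimodal in the first covariate,
# increasing in the second, graded soil preference. Coefficients are sharp
# enough that high suitability is confined to a minority of the landscape
# (mean s* ~ 0.2), the regime presence-only modelling is designed for.
default_true_niche <- function(config) {
  nms <- config$continuous_fields$name
  lin <- stats::setNames(rep(0, length(nms)), nms)
  qua <- lin
  lin[1] <- 5.0; qua[1] <- -3.5
  if (length(nms) >= 2) lin[2] <- 3.5
  off <- seq(1.5, -1.5, length.out = config$n_soil_classes)
  true_niche(intercept = -2.5, linear = lin, quadratic = qua, soil_offsets = off)
}

# evaluate the niche's linear predictor on a covariate table
niche_linear_predictor <- function(niche, covtab) {
  lp <- rep(niche$intercept, nrow(covtab))
  for (nm in names(niche$linear)) {
    x <- covtab[[nm]]
    lp <- lp + niche$linear[[nm]] * x + niche$quadratic[[nm]] * x^2
  }
  if (length(niche$soil_offsets) && !is.null(covtab$soil)) {
    code <- as.integer(as.character(covtab$soil))
    lp <- lp + niche$soil_offsets[code]
  }
  lp
}

#' Generate a synthetic landscape with known suitability
#'
#' Builds the continuous covariate fields as Gaussian random fields (scaled to
#' the configured mean/sd), carves spatially coherent soil patches by
#' quantile-slicing an auxiliary random field, and evaluates the true
#' suitability surface of the supplied (or default) niche.
#'
#' @param config a [landscape_config()].
#' @param niche a [true_niche()]; default is a strong unimodal niche.
#' @return list with elements `stack` (a `covariate_stack`), `niche`, and
#'   `true_suitability` (a `landsuit_grid` with values in (0, 1)).
#' @export
synth_landscape <- function(config = landscape_config(), niche = NULL) {
  stopifnot(inherits(config, "landscape_config"))
  if (is.null(niche)) niche <- default_true_niche(config)
  cf <- config$continuous_fields
  cont <- list()
  for (i in seq_len(nrow(cf))) {
    g <- gaussian_random_field(config$n_rows, config$n_cols, cf$range[i],
                               seed = config$seed + i,
                               cell_size = config$cell_size)
    g$values <- cf$mean[i] + cf$sd[i] * g$values
    cont[[cf$name[i]]] <- g
  }
  aux <- gaussian_random_field(config$n_rows, config$n_cols, config$soil_range,
                               seed = config$seed + nrow(cf) + 1L,
                               cell_size = config$cell_size)
  q <- stats::quantile(aux$values, probs = seq(0, 1, length.out = config$n_soil_classes + 1))
  codes <- as.numeric(cut(aux$values, breaks = q, labels = FALSE,
                          include.lowest = TRUE))
  soil <- new_grid(matrix(codes, config$n_rows, config$n_cols),
                   cell_size = config$cell_size)
  stack <- covariate_stack(cont, categorical = soil,
                           category_labels = paste0("soil_", seq_len(config$n_soil_classes)))
  covtab <- stack_table(stack, seq_len(config$n_rows * config$n_cols))
  s <- stats::plogis(niche_linear_predictor(niche, covtab))
  suit <- new_grid(matrix(s, config$n_rows, config$n_cols),
                   cell_size = config$cell_size)
  list(stack = stack, niche = niche, true_suitability = suit)
}

#' Sample presence records from a suitability surface
#'
#' Draws `n` distinct cells without replacement with probability proportional
#' to the cell's suitability and returns their centers as a point table.
#'
#' @param true_suitability a `landsuit_grid` with non-negative values.
#' @param n number of presences.
#' @param seed integer seed.
#' @param label record label.
#' @return data.frame with columns `lon`, `lat`, `label`.
#' @export
sample_presences <- function(true_suitability, n, seed = 1L, label = "presence") {
  stopifnot(is_grid(true_suitability), n >= 1)
  w <- true_suitability$values
  valid <- which(!is.na(w) & w > 0)
  if (n > length(valid)) {
    stop(sprintf("requested %d presences but only %d cells with positive suitability",
                 n, length(valid)), call. = FALSE)
  }
  cells <- local_seed(seed, sample_from(valid, n, prob = w[valid]))
  rc <- arrayInd(cells, c(true_suitability$n_rows, true_suitability$n_cols))
  cs <- true_suitability$cell_size
  data.frame(
    lon = true_suitability$x_ll + (rc[, 2] - 0.5) * cs,
    lat = true_suitability$y_ll + (true_suitability$n_rows - rc[, 1] + 0.5) * cs,
    label = label)
}

#' Population-generator parameters
#'
#' Parameters of the two-segment (breakpoint) relation between suitability and
#' population density on the log10(x+1) scale: intercept `a`, slope `b` below
#' the breakpoint `c`, slope `d` above it, and Gaussian noise sd `sigma`. The
#' mean function is continuous at the knot. Defaults encode a strong
#' dependence below the knot and a weak one above it, with the knot at 0.3.
#'
#' @param a intercept (log10 scale).
#' @param b slope below the breakpoint.
#' @param c breakpoint, strictly inside (0, 1).
#' @param d slope above the breakpoint.
#' @param sigma noise sd (log10 scale), >= 0.
#' @export
population_params <- function(a = 0.2, b = 6.0, c = 0.3, d = 0.5, sigma = 0.4) {
  if (!(c > 0 && c < 1)) stop("breakpoint c must lie strictly in (0,1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, sigma = sigma),
            class = "population_params")
}

# continuous two-segment mean on the log10(x+1) scale
segmented_mean <- function(x, a, b, c, d) a + b * pmin(x, c) + d * pmax(x - c, 0)

#' Generate a population-density grid from suitability
#'
#' Inverts the analysis model: on the log10(x+1) scale each cell's population
#' is the continuous two-segment function of suitability plus Gaussian noise;
#' the result is back-transformed (10^y - 1) and floored at zero. Cells with
#' zero population are retained.
#'
#' @param suitability a `landsuit_grid` with values in `[0, 1]`.
#' @param params a [population_params()].
#' @param seed integer seed.
#' @return a `landsuit_grid` of non-negative population densities.
#' @export
synth_population <- function(suitability, params = population_params(), seed = 1L) {
  stopifnot(is_grid(suitability), inherits(params, "population_params"))
  s <- suitability$values
  if (any(!is.na(s) & (s < 0 | s > 1))) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  y <- segmented_mean(s, params$a, params$b, params$c, params$d)
  if (params$sigma > 0) {
    noise <- local_seed(seed, stats::rnorm(length(y), sd = params$sigma))
    y <- y + matrix(noise, nrow(y), ncol(y))
  }
  out <- suitability
  out$values <- pmax(10^y - 1, 0)
  out
}

#' Conflict-generator parameters
#'
#' Logistic model for conflict occurrence as a function of shared suitability:
#' `P(conflict) = plogis(alpha + beta * ISS)` at each sampled locality.
#' Defaults give a strong positive ISS effect at 500 localities.
#'
#' @param alpha logistic intercept.
#' @param beta logistic coefficient on ISS.
#' @param n_points number of localities (>= 1).
#' @export
conflict_params <- function(alpha = -2.5, beta = 5, n_points = 500) {
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, n_points = as.integer(n_points)),
            class = "conflict_params")
}

#' Generate conflict/no-conflict localities from an ISS surface
#'
#' Samples `n_points` distinct valid cells uniformly and labels each
#' "conflict" with probability `plogis(alpha + beta * ISS)`, else
#' "no_conflict".
#'
#' @param iss a `landsuit_grid` of ISS values in `[0, 1]`.
#' @param params a [conflict_params()].
#' @param seed integer seed.
#' @return data.frame with columns `lon`, `lat`, `label`, `iss`.
#' @export
synth_conflicts <- function(iss, params = conflict_params(), seed = 1L) {
  stopifnot(is_grid(iss), inherits(params, "conflict_params"))
  valid <- which(!is.na(iss$values))
  if (params$n_points > length(valid)) {
    stop("n_points exceeds the number of valid cells", call. = FALSE)
  }
  res <- local_seed(seed, {
    cells <- sample_from(valid, params$n_points)
    p <- stats::plogis(params$alpha + params$beta * iss$values[cells])
    list(cells = cells, hit = stats::runif(length(cells)) < p)
  })
  rc <- arrayInd(res$cells, c(iss$n_rows, iss$n_cols))
  cs <- iss$cell_size
  data.frame(
    lon = iss$x_ll + (rc[, 2] - 0.5) * cs,
    lat = iss$y_ll + (iss$n_rows - rc[, 1] + 0.5) * cs,
    label = ifelse(res$hit, "conflict", "no_conflict"),
    iss = iss$values[res$cells])
}
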