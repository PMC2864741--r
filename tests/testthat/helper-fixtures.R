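# Small in-code fixtures shared across test files.

# a 1-layer stack around a given value matrix
wrap_stack <- function(values, cell_size = 1, name = "x") {
  cs <- covariate_stack(stats::setNames(list(new_grid(values, cell_size = cell_size)), name))
  cs
}

# a modest landscape with the default strong niche, memoised per (dims, seed)
fixture_cache <- new.env(parent = emptyenv())

small_world <- function(n = 60, seed = 7) {
  key <- paste0("w", n, "_", seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- synth_landscape(
      landscape_config(n_rows = n, n_cols = n, seed = seed))
  }
  fixture_cache[[key]]
}

# session temp file (cleaned up by R on exit)
scratch_file <- function() tempfile(fileext = ".asc")

# random grid mixing real values (6 significant digits), integers, and nodata
random_grid <- function(seed) {
  set.seed(seed)
  nr <- sample(1:12, 1)
  nc <- sample(1:12, 1)
  v <- matrix(signif(rnorm(nr * nc, sd = 10^sample(-3:3, 1)), 6), nr, nc)
  if (runif(1) < 0.3) v <- matrix(rpois(nr * nc, 20), nr, nc) * 1.0
  if (runif(1) < 0.5 && length(v) > 1) v[sample(length(v), max(1, length(v) %/% 5))] <- NA
  new_grid(v, x_ll = round(runif(1, -180, 180), 4), y_ll = round(runif(1, -90, 90), 4),
           cell_size = signif(runif(1, 0.01, 2), 6))
}

# one full default-configuration study, run once per test session
default_report <- function() {
  if (is.null(fixture_cache$report)) {
    fixture_cache$report <- suppressMessages(
      run_study(default_study_config(seed = 42), verbose = FALSE))
  }
  fixture_cache$report
}

# presence/background covariate tables from a landscape
world_design <- function(world, n_pres, n_bg, seed = 1L) {
  pres <- sample_presences(world$true_suitability, n_pres, seed = seed)
  list(presences = extract_at_points(world$stack, pres),
       background = build_background(world$stack, n_bg, seed = seed + 1L),
       points = pres)
}
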