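#' Derive a stage-specific seed from a master seed
#'
#' Hashes the stage name into the master seed so each stochastic stage gets
#' an independent, reproducible stream and adding a stage never perturbs the
#' streams of earlier stages. The result is always below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  mod <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% mod
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% mod
  }
  as.integer(h)
}

#' Uniform background sample for model fitting
#'
#' Background cells represent the available environment against which
#' presences are contrasted; they are drawn uniformly from the valid cells.
#' The conventional default is 10,000 cells, or every valid cell if the
#' stack has fewer.
#'
#' @param stack a `covariate_stack`.
#' @param n_background number of background cells.
#' @param seed integer seed.
#' @return covariate data.frame as from [sample_random_cells()].
#' @export
build_background <- function(stack, n_background = 10000, seed = 1L) {
  n_valid <- length(stack_valid_cells(stack))
  sample_random_cells(stack, min(n_background, n_valid), seed = seed)
}

#' Default study configuration
#'
#' A complete synthetic-study configuration: a 100 x 100 landscape with two
#' continuous climate fields and four soil classes; four landuse types
#' (agriculture, sedentary animal husbandry, nomadic pastoralism,
#' hunting-and-gathering) with distinct known niches and presence counts
#' spanning 47-290 records; cumulative-output thresholds per type;
#' breakpoint population generation (knot at 0.3); and a conflict stage with
#' a strong ISS effect at 500 localities.
#'
#' @param seed master seed.
#' @return nested list of class `study_config`.
#' @export
default_study_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    landscape = list(n_rows = 100, n_cols = 100, cell_size = 0.05,
                     n_soil_classes = 4, soil_range = 8,
                     continuous_fields = data.frame(
                       name = c("temperature", "precipitation"),
                       range = c(10, 15), mean = c(0, 0), sd = c(1, 1))),
    landuse_types = list(
      agriculture = list(
        n_presences = 290, threshold = 0.18,
        niche = list(intercept = -2.5,
                     linear = c(temperature = 4.0, precipitation = 3.0),
                     quadratic = c(temperature = -3.0, precipitation = 0),
                     soil_offsets = c(1.5, 0.5, -0.5, -1.5))),
      animal_husbandry = list(
        n_presences = 150, threshold = 0.13,
        niche = list(intercept = -2.0,
                     linear = c(temperature = 2.4, precipitation = 1.6),
                     quadratic = c(temperature = -2.0, precipitation = -1.0),
                     soil_offsets = c(0.5, 1.0, 0, -1.0))),
      nomadic_pastoralism = list(
        n_presences = 100, threshold = 0.09,
        niche = list(intercept = -2.0,
                     linear = c(temperature = 2.0, precipitation = -3.0),
                     quadratic = c(temperature = -1.6, precipitation = 0),
                     soil_offsets = c(-1.0, 0, 1.0, 0.5))),
      hunting_gathering = list(
        n_presences = 47, threshold = 0.10,
        niche = list(intercept = -2.0,
                     linear = c(temperature = -1.6, precipitation = 2.0),
                     quadratic = c(temperature = 0, precipitation = -1.2),
                     soil_offsets = c(-0.5, 0, 0.5, 1.0)))),
    model = list(beta = 1, k = 10, n_background = 5000, contribution_runs = 0),
    iss = list(formula = "minus_gap",
               pairs = list(c("agriculture", "nomadic_pastoralism"),
                            c("agriculture", "hunting_gathering"),
                            c("nomadic_pastoralism", "hunting_gathering"))),
    population = list(a = 0.2, b = 6.0, c = 0.3, d = 0.5, sigma = 0.4,
                      n_sample = 2000, n_classes = 10),
    gdp = list(enabled = TRUE, a = 0.3, b = 8.0, c = 0.1, d = 0.5,
               sigma = 0.5, n_sample = 2000, n_classes = 10),
    conflict = list(alpha = -2.5, beta = 5, n_points = 500,
                    max_eigenvectors = 5)),
    class = "study_config")
}

#' Read a study configuration file
#'
#' Reads a YAML key-value file and merges it over [default_study_config()],
#' so a config file only needs to state what differs from the defaults.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_study_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  cfg <- utils::modifyList(cfg, user)
  if (is.list(cfg$landscape$continuous_fields) &&
      !is.data.frame(cfg$landscape$continuous_fields)) {
    cfg$landscape$continuous_fields <-
      do.call(rbind, lapply(cfg$landscape$continuous_fields, as.data.frame))
  }
  class(cfg) <- "study_config"
  cfg
}

#' Validate a study configuration
#'
#' @param config a `study_config`.
#' @return character vector of problems, each naming the offending key;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  bad <- function(msg) problems <<- c(problems, msg)
  ls_ <- config$landscape
  if (is.null(ls_$n_rows) || ls_$n_rows < 10 ||
      is.null(ls_$n_cols) || ls_$n_cols < 10) {
    bad("landscape$n_rows/n_cols: must be at least 10")
  }
  if (!is.null(ls_$n_soil_classes) && ls_$n_soil_classes < 2) {
    bad("landscape$n_soil_classes: must be >= 2")
  }
  if (!length(config$landuse_types)) bad("landuse_types: none defined")
  for (nm in names(config$landuse_types)) {
    lt <- config$landuse_types[[nm]]
    if (is.null(lt$n_presences) || lt$n_presences < 5) {
      bad(sprintf("landuse_types$%s$n_presences: must be >= 5", nm))
    }
    if (is.null(lt$threshold) || lt$threshold < 0 || lt$threshold > 1) {
      bad(sprintf("landuse_types$%s$threshold: must lie in [0, 1]", nm))
    }
    if (!is.null(lt$presence_file) && !file.exists(lt$presence_file)) {
      bad(sprintf("landuse_types$%s$presence_file: file not found (%s)",
                  nm, lt$presence_file))
    }
  }
  if (!is.null(config$model$beta) && config$model$beta < 0) {
    bad("model$beta: must be >= 0")
  }
  if (!is.null(config$model$k) && config$model$k < 2) {
    bad("model$k: must be >= 2")
  }
  if (!config$iss$formula %in% iss_formulas()) {
    bad("iss$formula: unknown formula name")
  }
  for (pair in config$iss$pairs) {
    if (!all(pair %in% names(config$landuse_types))) {
      bad(sprintf("iss$pairs: undefined landuse type in pair (%s)",
                  paste(pair, collapse = ", ")))
    }
  }
  pp <- config$population
  if (!is.null(pp$c) && !(pp$c > 0 && pp$c < 1)) {
    bad("population$c: breakpoint must lie strictly in (0, 1)")
  }
  if (!is.null(pp$sigma) && pp$sigma < 0) bad("population$sigma: must be >= 0")
  if (!is.null(config$conflict$n_points) && config$conflict$n_points < 1) {
    bad("conflict$n_points: must be >= 1")
  }
  problems
}

config_niche <- function(defn) {
  true_niche(intercept = defn$intercept,
             linear = unlist(defn$linear),
             quadratic = unlist(defn$quadratic),
             soil_offsets = unlist(defn$soil_offsets))
}

# one population/GDP analysis block: sample cells, regress transformed
# response on modelled suitability, spatially corrected test, surfaces
density_analysis <- function(response_grid, suit_logistic, stack, pars, seed) {
  pts <- sample_random_cells(stack, pars$n_sample, seed = seed)
  cells_idx <- cell_index_at(stack_reference(stack), pts$lon, pts$lat)
  lin_idx <- (cells_idx$col - 1L) * stack_reference(stack)$n_rows + cells_idx$row
  x <- suit_logistic$grid$values[lin_idx]
  yv <- log10p1(response_grid$values[lin_idx])
  lin <- linear_fit(x, yv)
  brk <- breakpoint_fit(x, yv)
  aic <- compare_aic(list(linear = lin, breakpoint = brk))
  dut <- dutilleul_correlation(x, yv, cbind(pts$lon, pts$lat),
                               n_classes = pars$n_classes)
  predicted <- predict_surface(brk, suit_logistic)
  residuals <- residual_map(response_grid, predicted)
  list(sample = data.frame(lon = pts$lon, lat = pts$lat,
                           suitability = x, response_log = yv),
       linear = lin, breakpoint = brk, aic = aic, dutilleul = dut,
       predicted = predicted, residuals = residuals)
}

#' Run the full synthetic landuse study
#'
#' Executes the end-to-end analysis: landscape generation, presence sampling
#' from each landuse type's known niche, maximum-entropy model fitting with
#' cross-validated AUC (and optional permutation variable contributions),
#' logistic/cumulative surfaces and thresholded binary maps, deviation maps
#' against the ground-truth classification, ISS maps for the configured
#' pairs, population and (optionally) GDP regressions with Dutilleul-
#' corrected significance, and a conflict logistic regression with forward-
#' selected spatial eigenvectors. Every stochastic stage draws its seed from
#' the master seed via [derive_seed()], so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param config a `study_config` (see [default_study_config()]).
#' @param out_dir optional directory; when given, all surfaces are written as
#'   ESRI ASCII grids, tables as TSV, and a summary as YAML.
#' @param verbose log stage progress.
#' @return an object of class `study_report`.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL,
                      verbose = TRUE) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  master <- config$seed
  t0 <- Sys.time()

  say("[landscape] generating %d x %d synthetic landscape",
      config$landscape$n_rows, config$landscape$n_cols)
  ls_cfg <- landscape_config(
    n_rows = config$landscape$n_rows, n_cols = config$landscape$n_cols,
    cell_size = config$landscape$cell_size,
    seed = derive_seed(master, "landscape"),
    continuous_fields = config$landscape$continuous_fields,
    n_soil_classes = config$landscape$n_soil_classes,
    soil_range = config$landscape$soil_range)
  world <- synth_landscape(ls_cfg)   # stack + auxiliary true surface
  stack <- world$stack
  ref <- stack_reference(stack)
  all_cells <- seq_len(ref$n_rows * ref$n_cols)
  covtab_all <- stack_table(stack, all_cells)

  background <- build_background(stack, config$model$n_background,
                                 seed = derive_seed(master, "background"))

  landuse <- list()
  for (nm in names(config$landuse_types)) {
    lt <- config$landuse_types[[nm]]
    niche <- config_niche(lt$niche)
    s_true <- ref
    s_true$values <- matrix(stats::plogis(niche_linear_predictor(niche, covtab_all)),
                            ref$n_rows, ref$n_cols)
    say("[%s] sampling %d presences and fitting the niche model", nm, lt$n_presences)
    pres_pts <- if (!is.null(lt$presence_file)) {
      read_point_table(lt$presence_file)
    } else {
      sample_presences(s_true, lt$n_presences,
                       seed = derive_seed(master, paste0("presence_", nm)))
    }
    pres_cov <- extract_at_points(stack, pres_pts)
    pres_cov <- pres_cov[pres_cov$in_extent & !pres_cov$on_nodata, , drop = FALSE]
    fit <- fit_maxent(pres_cov, background, beta = config$model$beta)
    raw <- predict_raw(fit, stack)
    logistic <- to_logistic(raw)
    cumulative <- to_cumulative(raw)
    binary <- apply_threshold(cumulative, lt$threshold)
    evaluation <- crossval_auc(pres_cov, background, k = config$model$k,
                               seed = derive_seed(master, paste0("cv_", nm)),
                               beta = config$model$beta)
    contributions <- if (config$model$contribution_runs > 0) {
      variable_contributions(pres_cov, background,
                             n_runs = config$model$contribution_runs,
                             seed = derive_seed(master, paste0("contrib_", nm)),
                             beta = config$model$beta)
    } else NULL
    reference_binary <- s_true
    reference_binary$values <- (s_true$values >= 0.5) * 1
    deviation <- deviation_map(binary, reference_binary)
    recovery <- stats::cor(logistic$grid$values[all_cells],
                           s_true$values[all_cells], method = "spearman")
    landuse[[nm]] <- list(
      presences = pres_pts, model = fit, logistic = logistic,
      cumulative = cumulative, binary = binary, true_suitability = s_true,
      evaluation = evaluation, contributions = contributions,
      deviation = deviation, recovery_spearman = recovery,
      threshold = lt$threshold)
    say("[%s] mean AUC %.3f, Spearman vs truth %.3f", nm,
        evaluation$mean_auc, recovery)
  }

  say("[iss] computing %d shared-suitability map(s)", length(config$iss$pairs))
  iss_maps <- list()
  for (pair in config$iss$pairs) {
    key <- paste(pair, collapse = "__")
    iss_maps[[key]] <- compute_iss(landuse[[pair[1]]]$logistic,
                                   landuse[[pair[2]]]$logistic,
                                   formula = config$iss$formula,
                                   lut1_name = pair[1], lut2_name = pair[2])
  }

  say("[population] breakpoint generation and spatially corrected regression")
  agr <- landuse[[1]]
  pp <- config$population
  pop_grid <- synth_population(agr$true_suitability,
                               population_params(pp$a, pp$b, pp$c, pp$d, pp$sigma),
                               seed = derive_seed(master, "population"))
  population <- density_analysis(pop_grid, agr$logistic, stack, pp,
                                 seed = derive_seed(master, "population_sample"))

  gdp <- NULL
  if (isTRUE(config$gdp$enabled)) {
    say("[gdp] same machinery on the wealth response")
    gp <- config$gdp
    gdp_grid <- synth_population(agr$true_suitability,
                                 population_params(gp$a, gp$b, gp$c, gp$d, gp$sigma),
                                 seed = derive_seed(master, "gdp"))
    gdp <- density_analysis(gdp_grid, agr$logistic, stack, gp,
                            seed = derive_seed(master, "gdp_sample"))
  }

  say("[conflict] logistic test of ISS with spatial eigenvectors")
  cf <- config$conflict
  iss1 <- iss_maps[[1]]$grid
  conflicts <- synth_conflicts(iss1, conflict_params(cf$alpha, cf$beta, cf$n_points),
                               seed = derive_seed(master, "conflict"))
  ybin <- as.numeric(conflicts$label == "conflict")
  base_fit <- logistic_fit(data.frame(iss = conflicts$iss), ybin)
  basis <- mem_basis(cbind(conflicts$lon, conflicts$lat))
  sel <- select_eigenvectors(basis, stats::residuals(base_fit$glm, type = "pearson"),
                             max_k = cf$max_eigenvectors,
                             seed = derive_seed(master, "mem_select"))
  X <- data.frame(iss = conflicts$iss)
  if (length(sel$selected)) {
    X <- cbind(X, as.data.frame(basis$vectors[, sel$selected, drop = FALSE]))
  }
  conflict_fit <- logistic_fit(X, ybin)

  report <- structure(list(
    config = config,
    landscape = world,
    background = background,
    landuse = landuse,
    iss = iss_maps,
    population = population,
    gdp = gdp,
    conflict = list(points = conflicts, fit = conflict_fit,
                    base_fit = base_fit, eigenvectors = sel$selected,
                    moran_path = sel$moran_path),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in names(x$landuse)) {
    cat(sprintf("  %-22s AUC %.3f  Spearman %.3f  deviations %d\n", nm,
                x$landuse[[nm]]$evaluation$mean_auc,
                x$landuse[[nm]]$recovery_spearman,
                sum(x$landuse[[nm]]$deviation$counts[c("model_only", "reference_only")])))
  }
  cat(sprintf("  population: linear r2 %.3f, breakpoint r2 %.3f at c = %.3f\n",
              x$population$linear$r2, x$population$breakpoint$r2,
              x$population$breakpoint$c))
  d <- x$population$dutilleul
  cat(sprintf("  Dutilleul: F_adj %.1f, df_adj %.1f, p %.3g\n", d$F_adj, d$df_adj, d$p))
  cf <- x$conflict$fit
  cat(sprintf("  conflict: chi2 %.1f, ISS z %.2f (p %.3g), accuracy %.2f, %d eigenvector(s)\n",
              cf$chisq, cf$coefficients["iss", "z"], cf$coefficients["iss", "p"],
              cf$accuracy, length(x$conflict$eigenvectors)))
  invisible(x)
}

#' Write all study outputs to a directory
#'
#' Surfaces as ESRI ASCII grids, fit tables and point tables as TSV, and a
#' YAML summary of the headline numbers.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, paste0(...))
  for (nm in names(report$landuse)) {
    lu <- report$landuse[[nm]]
    write_ascii_grid(lu$logistic$grid, fp(nm, "_logistic.asc"))
    write_ascii_grid(lu$cumulative$grid, fp(nm, "_cumulative.asc"))
    write_ascii_grid(lu$binary, fp(nm, "_binary.asc"))
    write_ascii_grid(lu$deviation$grid, fp(nm, "_deviation.asc"))
    write_point_table(lu$presences, fp(nm, "_presences.csv"))
  }
  for (key in names(report$iss)) {
    write_ascii_grid(report$iss[[key]]$grid, fp("iss_", key, ".asc"))
  }
  write_ascii_grid(report$population$predicted, fp("population_predicted.asc"))
  write_ascii_grid(report$population$residuals, fp("population_residuals.asc"))
  utils::write.table(report$population$sample, fp("population_sample.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_point_table(report$conflict$points, fp("conflict_points.csv"))
  summary <- list(
    landuse = lapply(report$landuse, function(lu) list(
      mean_auc = lu$evaluation$mean_auc,
      recovery_spearman = lu$recovery_spearman,
      threshold = lu$threshold,
      deviation_counts = as.list(lu$deviation$counts))),
    population = list(
      linear_r2 = report$population$linear$r2,
      breakpoint = report$population$breakpoint[c("a", "b", "c", "d", "r2")],
      dAIC = report$population$aic$dAIC[2],
      dutilleul = report$population$dutilleul[c("r", "r2", "F_adj", "df_adj", "p")]),
    conflict = list(
      chisq = report$conflict$fit$chisq,
      accuracy = report$conflict$fit$accuracy,
      iss_p = unname(report$conflict$fit$coefficients["iss", "p"]),
      n_eigenvectors = length(report$conflict$eigenvectors)))
  if (!is.null(report$gdp)) {
    summary$gdp <- list(linear_r2 = report$gdp$linear$r2,
                        breakpoint_r2 = report$gdp$breakpoint$r2,
                        breakpoint_c = report$gdp$breakpoint$c)
  }
  yaml::write_yaml(summary, fp("study_summary.yaml"))
  invisible(out_dir)
}
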