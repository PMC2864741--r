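#' Raster grid objects
#'
#' A `landsuit_grid` is a lightweight in-memory raster: a numeric matrix whose
#' first row is the northernmost row, plus the georeferencing header of an
#' ESRI ASCII grid (lower-left corner, square cell size in degrees, nodata
#' sentinel). Nodata cells are stored as `NA` internally; the sentinel is only
#' used on disk.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` marks nodata.
#' @param x_ll,y_ll longitude/latitude of the lower-left corner (degrees).
#' @param cell_size cell side length in degrees; must be positive.
#' @param nodata sentinel value written to file for `NA` cells.
#' @return An object of class `landsuit_grid`.
#' @examples
#' g <- new_grid(matrix(1:4, 2, 2), 0, 0, 0.5)
#' grid_values(g)
#' @export
new_grid <- function(values, x_ll = 0, y_ll = 0, cell_size = 1, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (any(!is.na(values) & !is.finite(values))) {
    stop("grid values must be finite or NA (nodata)", call. = FALSE)
  }
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         x_ll = as.numeric(x_ll), y_ll = as.numeric(y_ll),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata)),
    class = "landsuit_grid")
}

#' @rdname new_grid
#' @param x object to test or extract from.
#' @export
is_grid <- function(x) inherits(x, "landsuit_grid")

#' @rdname new_grid
#' @export
grid_values <- function(x) x$values

#' @export
print.landsuit_grid <- function(x, ...) {
  cat(sprintf("<landsuit_grid> %d x %d cells, cell_size %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  valid cells: %d, range [%g, %g]\n", length(v), min(v), max(v)))
  } else {
    cat("  no valid cells\n")
  }
  invisible(x)
}

# shared geometry check; tolerance absorbs header round-tripping
grids_congruent <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_ll - b$x_ll) < tol && abs(a$y_ll - b$y_ll) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_incongruent <- function(a, b, what = "grids") {
  if (!grids_congruent(a, b)) {
    stop(sprintf("%s are not congruent (dimensions/origin/cell size differ)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-center coordinates of every cell
#'
#' Returns longitude and latitude of cell centers, in the row-major order of
#' the value matrix (row 1 is the northernmost row).
#'
#' @param grid a `landsuit_grid`.
#' @return data.frame with columns `lon`, `lat`, `row`, `col`.
#' @export
cell_centers <- function(grid) {
  cs <- grid$cell_size
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  data.frame(
    lon = grid$x_ll + (col - 0.5) * cs,
    lat = grid$y_ll + (grid$n_rows - row + 0.5) * cs,
    row = row, col = col)
}

# Half-open cell assignment: cells cover [x, x + cs) x (y, y + cs], so a point
# on a shared vertical edge belongs to the cell to its east and a point on a
# horizontal edge to the cell to its south. Returns row/col or NA when outside.
cell_index_at <- function(grid, lon, lat) {
  cs <- grid$cell_size
  col <- floor((lon - grid$x_ll) / cs) + 1
  k <- ceiling((lat - grid$y_ll) / cs)   # cells counted from the bottom
  row <- grid$n_rows - k + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

format_grid_value <- function(v, nodata, digits) {
  out <- character(length(v))
  na <- is.na(v)
  out[na] <- format_num(nodata, digits)
  out[!na] <- format_num(v[!na], digits)
  out
}

format_num <- function(v, digits) {
  whole <- v == trunc(v) & abs(v) < 1e15
  out <- sprintf(paste0("%.", digits, "g"), v)
  out[whole] <- sprintf("%.0f", v[whole])
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by whitespace-separated cell values in
#' row-major order, northernmost row first. Cells equal to the nodata sentinel
#' become `NA`.
#'
#' @param path file path.
#' @return a `landsuit_grid`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: fewer than 7 lines", call. = FALSE)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  hdr <- numeric(6)
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L || tolower(parts[1]) != keys[i]) {
      stop(sprintf("malformed header line %d: expected '%s', got '%s'",
                   i, keys[i], lines[i]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop(sprintf("malformed header line %d: non-numeric value '%s'", i, parts[2]),
           call. = FALSE)
    }
    hdr[i] <- val
  }
  nc <- as.integer(hdr[1]); nr <- as.integer(hdr[2])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("truncated grid: expected %d values (%d x %d), found %d",
                 nr * nc, nr, nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr[6]] <- NA_real_
  new_grid(m, x_ll = hdr[3], y_ll = hdr[4], cell_size = hdr[5], nodata = hdr[6])
}

#' Write an ESRI ASCII grid
#'
#' Writes a `landsuit_grid` in the format read by [read_ascii_grid()]. Real
#' values are printed with `digits` significant digits (default 6); whole
#' numbers and the nodata sentinel are written verbatim without a decimal
#' point. A value already representable at the configured precision
#' round-trips exactly.
#'
#' @param grid a `landsuit_grid`.
#' @param path output file path.
#' @param digits significant digits for non-integer values.
#' @export
write_ascii_grid <- function(grid, path, digits = 6) {
  stopifnot(is_grid(grid))
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %s", format_num(grid$x_ll, 15)),
    sprintf("yllcorner %s", format_num(grid$y_ll, 15)),
    sprintf("cellsize %s", format_num(grid$cell_size, 15)),
    sprintf("NODATA_value %s", format_num(grid$nodata, 15)))
  rows <- apply(grid$values, 1L, function(r) {
    paste(format_grid_value(r, grid$nodata, digits), collapse = " ")
  })
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Covariate stacks
#'
#' Bundles congruent continuous covariate grids with an optional categorical
#' (integer-coded) grid. A cell that is nodata in any member is nodata in all
#' (intersection mask).
#'
#' @param continuous named list of `landsuit_grid`s with continuous values.
#' @param categorical optional `landsuit_grid` of integer class codes.
#' @param category_labels optional character vector naming the codes.
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(continuous, categorical = NULL, category_labels = NULL) {
  if (!length(continuous) || is.null(names(continuous)) ||
      any(!nzchar(names(continuous)))) {
    stop("continuous must be a non-empty named list of grids", call. = FALSE)
  }
  ref <- continuous[[1]]
  for (g in continuous) stop_if_incongruent(ref, g, "stack members")
  if (!is.null(categorical)) {
    stop_if_incongruent(ref, categorical, "stack members")
    v <- categorical$values
    if (any(!is.na(v) & v != round(v))) {
      stop("categorical grid must hold integer codes", call. = FALSE)
    }
  }
  # intersection mask: propagate any member's nodata to all members
  na_mask <- Reduce(`|`, lapply(continuous, function(g) is.na(g$values)))
  if (!is.null(categorical)) na_mask <- na_mask | is.na(categorical$values)
  continuous <- lapply(continuous, function(g) {
    g$values[na_mask] <- NA_real_
    g
  })
  if (!is.null(categorical)) categorical$values[na_mask] <- NA_real_
  structure(
    list(continuous = continuous, categorical = categorical,
         category_labels = category_labels),
    class = "covariate_stack")
}

#' @rdname covariate_stack
#' @param x object to test.
#' @export
is_covariate_stack <- function(x) inherits(x, "covariate_stack")

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d continuous layer(s): %s\n",
              length(x$continuous), paste(names(x$continuous), collapse = ", ")))
  if (!is.null(x$categorical)) {
    codes <- sort(unique(stats::na.omit(c(x$categorical$values))))
    cat(sprintf("  categorical layer with %d class(es)\n", length(codes)))
  }
  ref <- x$continuous[[1]]
  cat(sprintf("  %d x %d cells, %d valid\n", ref$n_rows, ref$n_cols,
              sum(!is.na(ref$values))))
  invisible(x)
}

stack_reference <- function(stack) stack$continuous[[1]]

stack_covariate_names <- function(stack) {
  c(names(stack$continuous), if (!is.null(stack$categorical)) "soil")
}

# linear cell indices (column-major into the value matrix) of valid cells
stack_valid_cells <- function(stack) which(!is.na(stack_reference(stack)$values))

# covariate data.frame for the given linear cell indices; categorical as factor
stack_table <- function(stack, cells) {
  ref <- stack_reference(stack)
  rc <- arrayInd(cells, c(ref$n_rows, ref$n_cols))
  out <- data.frame(
    lon = ref$x_ll + (rc[, 2] - 0.5) * ref$cell_size,
    lat = ref$y_ll + (ref$n_rows - rc[, 1] + 0.5) * ref$cell_size)
  for (nm in names(stack$continuous)) out[[nm]] <- stack$continuous[[nm]]$values[cells]
  if (!is.null(stack$categorical)) {
    out$soil <- factor(stack$categorical$values[cells])
  }
  out
}

#' Sample random cells from a covariate stack
#'
#' Draws `n` distinct non-nodata cells uniformly without replacement and
#' returns their center coordinates and covariate values. Reproducible for a
#' fixed seed.
#'
#' @param stack a `covariate_stack`.
#' @param n number of cells to draw.
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat` and one column per covariate.
#' @export
sample_random_cells <- function(stack, n, seed = 1L) {
  stopifnot(is_covariate_stack(stack))
  valid <- stack_valid_cells(stack)
  if (n > length(valid)) {
    stop(sprintf("requested %d cells but only %d valid cells available",
                 n, length(valid)), call. = FALSE)
  }
  cells <- local_seed(seed, sample_from(valid, n))
  stack_table(stack, cells)
}

#' Extract covariate values at point locations
#'
#' Maps each point to the cell containing it under the half-open rule
#' (a point on a shared edge belongs to the cell to its east/south) and
#' returns that cell's covariate values. Points outside the extent or on
#' nodata cells are flagged, not dropped.
#'
#' @param stack a `covariate_stack`.
#' @param points data.frame with `lon` and `lat` columns (a point table).
#' @return data.frame: the input coordinates, covariates, and logical columns
#'   `in_extent` and `on_nodata`.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(is_covariate_stack(stack))
  if (!all(c("lon", "lat") %in% names(points))) {
    stop("points must have lon and lat columns", call. = FALSE)
  }
  ref <- stack_reference(stack)
  idx <- cell_index_at(ref, points$lon, points$lat)
  inb <- !is.na(idx$row)
  cells <- rep(NA_integer_, nrow(points))
  cells[inb] <- (idx$col[inb] - 1L) * ref$n_rows + idx$row[inb]
  out <- data.frame(lon = points$lon, lat = points$lat)
  for (nm in names(stack$continuous)) {
    v <- rep(NA_real_, nrow(points))
    v[inb] <- stack$continuous[[nm]]$values[cells[inb]]
    out[[nm]] <- v
  }
  if (!is.null(stack$categorical)) {
    v <- rep(NA_real_, nrow(points))
    v[inb] <- stack$categorical$values[cells[inb]]
    out$soil <- factor(v)
  }
  out$in_extent <- inb
  out$on_nodata <- inb & is.na(ref$values[ifelse(inb, cells, 1L)])
  out
}

#' Point-table input/output
#'
#' Point tables are delimited text files with a header `lon,lat,label`:
#' presence records of a landuse type, or conflict/no-conflict localities.
#'
#' @param path file path.
#' @param points data.frame with columns `lon`, `lat`, `label`.
#' @param sep field separator.
#' @return `read_point_table` returns a data.frame with columns `lon`
#'   (numeric), `lat` (numeric), `label` (character).
#' @export
read_point_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("lon", "lat", "label")
  if (!all(need %in% names(tab))) {
    stop("point table must have columns lon, lat, label", call. = FALSE)
  }
  tab[need]
}

#' @rdname read_point_table
#' @export
write_point_table <- function(points, path, sep = ",") {
  stopifnot(all(c("lon", "lat", "label") %in% names(points)))
  utils::write.table(points[c("lon", "lat", "label")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sample n elements of v (safe when length(v) == 1, unlike sample())
sample_from <- function(v, n, prob = NULL) v[sample.int(length(v), n, prob = prob)]

#' Evaluate code under a locally set RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so seeded helpers never perturb the surrounding random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
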