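#' Index of shared suitability (ISS)
#'
#' ISS scores each cell by how strongly two landuse types are *both* suited
#' to it: values near one where both suitabilities are high and similar, near
#' zero where one type is clearly better than the other or where both are
#' poor. High ISS flags cells where different landuse traditions compete for
#' the same ground.
#'
#' Three formulas are shipped, all symmetric with range `[0,1]`:
#' \describe{
#'   \item{`minus_gap` (default)}{`max(0, min(s1,s2) - |s1-s2|)`}
#'   \item{`harmonic`}{`2*s1*s2/(s1+s2)` (0 when both are 0)}
#'   \item{`product`}{`s1*s2*(1-|s1-s2|)`}
#' }
#' The formula is name-selected so an alternative definition can be dropped
#' in without touching callers.
#'
#' @param s1,s2 `suitability_surface`s of the same flavor (logistic
#'   recommended) or congruent `landsuit_grid`s with values in `[0,1]`.
#' @param formula formula name.
#' @return an object of class `iss_grid`: a list with `grid` (the ISS
#'   values), `formula`, and the input labels `lut1_name`/`lut2_name`.
#' @param lut1_name,lut2_name labels for the two landuse types.
#' @export
compute_iss <- function(s1, s2, formula = c("minus_gap", "harmonic", "product"),
                        lut1_name = "lut1", lut2_name = "lut2") {
  formula <- match.arg(formula)
  if (inherits(s1, "suitability_surface") || inherits(s2, "suitability_surface")) {
    if (!(inherits(s1, "suitability_surface") && inherits(s2, "suitability_surface"))) {
      stop("both inputs must be suitability surfaces (or both plain grids)",
           call. = FALSE)
    }
    if (s1$flavor != s2$flavor) {
      stop(sprintf("flavor mismatch: '%s' vs '%s'", s1$flavor, s2$flavor),
           call. = FALSE)
    }
    g1 <- s1$grid; g2 <- s2$grid
  } else {
    g1 <- s1; g2 <- s2
  }
  stopifnot(is_grid(g1), is_grid(g2))
  stop_if_incongruent(g1, g2, "suitability grids")
  a <- g1$values; b <- g2$values
  if (any(!is.na(a) & (a < 0 | a > 1)) || any(!is.na(b) & (b < 0 | b > 1))) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  v <- iss_formula(formula)(a, b)
  out <- g1
  out$values <- matrix(v, nrow(a), ncol(a))   # pmax() may drop dim attributes
  structure(list(grid = out, formula = formula,
                 lut1_name = lut1_name, lut2_name = lut2_name),
            class = "iss_grid")
}

# vectorized ISS kernels; all symmetric, [0,1]-valued
iss_formula <- function(name) {
  switch(name,
    minus_gap = function(a, b) pmax(0, pmin(a, b) - abs(a - b)),
    harmonic = function(a, b) ifelse(a + b == 0, 0, 2 * a * b / (a + b)),
    product = function(a, b) a * b * (1 - abs(a - b)),
    stop("unknown ISS formula: ", name, call. = FALSE))
}

#' Names of the shipped ISS formulas
#' @return character vector of formula names accepted by [compute_iss()].
#' @export
iss_formulas <- function() c("minus_gap", "harmonic", "product")

#' @export
print.iss_grid <- function(x, ...) {
  cat(sprintf("<iss_grid> %s vs %s (formula: %s)\n",
              x$lut1_name, x$lut2_name, x$formula))
  print(x$grid)
  invisible(x)
}

#' Deviation map between a model prediction and a reference classification
#'
#' Compares two congruent binary grids cell by cell and codes the result:
#' 0 = both absent, 1 = both present, 2 = model-only (model predicts presence
#' where the reference shows absence), 3 = reference-only (reference shows
#' presence the model misses). Nodata in either input propagates.
#'
#' @param model_binary binary `landsuit_grid` (the thresholded prediction).
#' @param reference_binary binary `landsuit_grid` (the reference landuse map).
#' @return an object of class `deviation_grid` with elements `grid` and
#'   `counts` (named cells-per-code table over valid cells).
#' @export
deviation_map <- function(model_binary, reference_binary) {
  stopifnot(is_grid(model_binary), is_grid(reference_binary))
  stop_if_incongruent(model_binary, reference_binary, "deviation inputs")
  m <- model_binary$values
  r <- reference_binary$values
  if (any(!is.na(m) & !(m %in% c(0, 1))) || any(!is.na(r) & !(r %in% c(0, 1)))) {
    stop("deviation_map requires binary (0/1) grids", call. = FALSE)
  }
  code <- matrix(NA_real_, nrow(m), ncol(m))
  ok <- !is.na(m) & !is.na(r)
  code[ok & m == 0 & r == 0] <- 0
  code[ok & m == 1 & r == 1] <- 1
  code[ok & m == 1 & r == 0] <- 2
  code[ok & m == 0 & r == 1] <- 3
  g <- model_binary
  g$values <- code
  counts <- vapply(0:3, function(k) sum(code == k, na.rm = TRUE), numeric(1))
  names(counts) <- c("agree_absence", "agree_presence", "model_only",
                     "reference_only")
  structure(list(grid = g, counts = counts), class = "deviation_grid")
}

#' @export
print.deviation_grid <- function(x, ...) {
  cat("<deviation_grid>\n")
  print(x$counts)
  invisible(x)
}
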