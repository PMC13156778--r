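#' Define a process factor
#'
#' A factor is described by its center point and the actual-unit change that
#' corresponds to one coded unit, so that `actual = center + coded * step`.
#' `decimals` is the number of decimal places used when actual levels are
#' reported (rounding is half-up, see [round_half_up()]).
#'
#' @param name Factor name (used as a column suffix in design tables).
#' @param units Physical units, e.g. `"min"` or `"mol/L"`.
#' @param center Actual value at coded level 0.
#' @param step Actual change per coded unit; must be positive.
#' @param decimals Number of decimals for reported actual levels.
#'
#' @return A one-row tibble with columns `name`, `units`, `center`, `step`,
#'   `decimals`. Bind rows of these to build a factor table.
#' @export
#' @examples
#' factor_spec("power", "W", center = 400, step = 100, decimals = 1)
factor_spec <- function(name, units, center, step, decimals = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(step) || step <= 0) {
    abort(sprintf("`step` for factor '%s' must be a positive number.", name))
  }
  if (decimals < 0 || decimals != round(decimals)) {
    abort("`decimals` must be a non-negative integer.")
  }
  tibble::tibble(
    name = name, units = units,
    center = as.numeric(center), step = as.numeric(step),
    decimals = as.integer(decimals)
  )
}

#' Six-factor table for ultrasonic-assisted alkaline extraction
#'
#' The factor table used throughout the package examples: soaking time,
#' NaOH concentration, ultrasonic time, liquid-solid ratio, ultrasonic power
#' and ultrasonic temperature, centred on the single-factor optima with the
#' steps that reproduce the published five-level central composite design
#' (axial distance `6^(1/4)`).
#'
#' @return A six-row factor tibble (see [factor_spec()]).
#' @export
#' @examples
#' crp_factors()
crp_factors <- function() {
  dplyr::bind_rows(
    factor_spec("soak_time",  "min",   center = 120, step = 60,  decimals = 1L),
    factor_spec("naoh",       "mol/L", center = 0.5, step = 0.1, decimals = 2L),
    factor_spec("sonic_time", "min",   center = 30,  step = 10,  decimals = 1L),
    factor_spec("ls_ratio",   "mL/g",  center = 25,  step = 5,   decimals = 1L),
    factor_spec("power",      "W",     center = 400, step = 100, decimals = 1L),
    factor_spec("temp",       "degC",  center = 60,  step = 10,  decimals = 1L)
  )
}

#' Axial distances for central composite designs
#'
#' `practical_alpha()` returns the "practical" axial distance `k^(1/4)`,
#' which keeps star points close to the operating region when the number of
#' factors is large. `rotatable_alpha()` returns `F^(1/4)` where `F` is the
#' factorial run count, the classical rotatability condition.
#'
#' @param k Number of factors (integer, at least 2).
#' @param n_factorial Factorial run count `F` (for a full design, `2^k`).
#'
#' @return The axial distance as a single number.
#' @export
#' @examples
#' practical_alpha(6)    # 1.5651
#' rotatable_alpha(4)    # sqrt(2)
practical_alpha <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 2) {
    abort("`k` must be a single integer >= 2.")
  }
  k^0.25
}

#' @rdname practical_alpha
#' @export
rotatable_alpha <- function(n_factorial) {
  if (length(n_factorial) != 1L || !is.finite(n_factorial) ||
      n_factorial != round(n_factorial) || n_factorial < 2) {
    abort("`n_factorial` must be a single integer >= 2.")
  }
  n_factorial^0.25
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (half-up for positive
#' numbers), the convention used for reported factor levels and practical
#' operating settings; `base::round()` rounds ties to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(26.35, 1)  # 26.4
#' round(26.35, 1)          # 26.3 under round-to-even (binary aside)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert between coded and actual factor levels
#'
#' Coded level 0 maps to the factor center and one coded unit to one `step`
#' in actual units. `coded_to_actual()` optionally rounds to each factor's
#' reporting precision; `actual_to_coded()` inverts the affine map exactly.
#'
#' @param factors Factor table (rows from [factor_spec()]).
#' @param coded,actual Numeric matrix or data frame with one column per
#'   factor (in factor-table order), or a vector of length `nrow(factors)`.
#' @param round Should actual values be rounded to `decimals`? Default `FALSE`.
#'
#' @return A numeric matrix with one column per factor.
#' @export
#' @examples
#' f <- crp_factors()
#' coded_to_actual(f, rep(0, 6), round = TRUE)
coded_to_actual <- function(factors, coded, round = FALSE) {
  coded <- as_factor_matrix(coded, factors)
  actual <- sweep(sweep(coded, 2, factors$step, `*`), 2, factors$center, `+`)
  if (round) {
    for (j in seq_len(ncol(actual))) {
      actual[, j] <- round_half_up(actual[, j], factors$decimals[j])
    }
  }
  actual
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(factors, actual) {
  actual <- as_factor_matrix(actual, factors)
  sweep(sweep(actual, 2, factors$center, `-`), 2, factors$step, `/`)
}

as_factor_matrix <- function(x, factors) {
  k <- nrow(factors)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k) abort(sprintf("Expected %d factor values, got %d.", k, length(x)))
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != k) abort(sprintf("Expected %d factor columns, got %d.", k, ncol(x)))
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("Factor levels must be finite.")
  colnames(x) <- factors$name
  x
}

#' Build a full central composite design
#'
#' Generates the classical three-block central composite design: all `2^k`
#' factorial corners at coded +/-1, `2k` axial (star) runs at +/-alpha on one
#' axis, and `n_center` replicated center runs. Run order is randomized with
#' a Fisher-Yates shuffle driven by `seed`; the set of runs itself does not
#' depend on the seed.
#'
#' @param factors Factor table (rows from [factor_spec()]).
#' @param alpha Either `"practical"` (`k^(1/4)`, default), `"rotatable"`
#'   (`(2^k)^(1/4)`), or an explicit positive number.
#' @param n_center Number of center replicates (>= 1).
#' @param seed Integer seed for the run-order shuffle.
#'
#' @return A tibble of class `ccd_design` with columns `run_id`, `run_type`
#'   (`factorial`/`axial`/`center`), `coded_<name>` and `actual_<name>` for
#'   each factor, plus attributes `factors`, `alpha`, `n_center`, `seed`.
#' @export
#' @examples
#' des <- ccd_design(crp_factors(), n_center = 10, seed = 42)
#' nrow(des)                # 86 = 2^6 + 12 + 10
#' table(des$run_type)
ccd_design <- function(factors, alpha = c("practical", "rotatable"),
                       n_center = 10L, seed = 1L) {
  k <- nrow(factors)
  if (k < 2 || k > 8) abort("Full-factorial CCDs are supported for 2 to 8 factors.")
  if (any(factors$step <= 0)) abort("All factor steps must be positive.")
  if (n_center < 1) abort("`n_center` must be at least 1.")
  if (is.character(alpha)) {
    alpha <- match.arg(alpha)
    alpha <- if (alpha == "practical") practical_alpha(k) else rotatable_alpha(2^k)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("`alpha` must be \"practical\", \"rotatable\", or a positive number.")
  }

  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)
  coded <- rbind(corners, axial, center)
  run_type <- rep(c("factorial", "axial", "center"),
                  times = c(nrow(corners), nrow(axial), n_center))

  ord <- withr_seed(seed, sample.int(nrow(coded)))
  coded <- coded[ord, , drop = FALSE]
  run_type <- run_type[ord]

  colnames(coded) <- factors$name
  actual <- coded_to_actual(factors, coded, round = TRUE)

  out <- tibble::tibble(run_id = seq_len(nrow(coded)), run_type = run_type)
  for (j in seq_len(k)) out[[paste0("coded_", factors$name[j])]] <- coded[, j]
  for (j in seq_len(k)) out[[paste0("actual_", factors$name[j])]] <- actual[, j]
  structure(out,
    class = c("ccd_design", class(out)),
    factors = factors, alpha = alpha, n_center = as.integer(n_center),
    seed = as.integer(seed)
  )
}

# Evaluate an expression with a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Extract the coded or actual design matrix from a design tibble
#'
#' @param design A [ccd_design()] tibble (or any tibble with the same
#'   column naming scheme).
#' @param which `"coded"` or `"actual"`.
#' @return Numeric matrix with factor names as columns.
#' @export
design_matrix <- function(design, which = c("coded", "actual")) {
  which <- match.arg(which)
  cols <- grep(paste0("^", which, "_"), names(design), value = TRUE)
  if (length(cols) == 0L) abort(sprintf("No `%s_*` columns found.", which))
  m <- as.matrix(design[cols])
  colnames(m) <- sub(paste0("^", which, "_"), "", cols)
  m
}
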