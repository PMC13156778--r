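#' Maximize a surrogate over box constraints by multistart local search
#'
#' Seeds `n_starts` Latin-hypercube points in the box, polishes each with
#' projected quasi-Newton ascent (`L-BFGS-B` on the negated objective,
#' finite-difference gradients), and returns the best point seen across all
#' starts and polish iterates. Deterministic under `seed`. Starts where the
#' objective is non-finite are skipped.
#'
#' @param predict_fn Function taking a length-`k` numeric vector (or 1-row
#'   matrix) and returning a single finite objective value.
#' @param bounds `k x 2` matrix (or list of pairs) of lower/upper bounds.
#' @param n_starts Number of Latin-hypercube starts (default 64).
#' @param seed Integer seed.
#'
#' @return A list of class `optimum_result`: `par` (argmax), `value`,
#'   `n_starts`, `seed`, `starts` (tibble of start points and their polished
#'   values).
#' @export
#' @examples
#' opt <- maximize_surrogate(function(x) -(x[1] - 0.3)^2,
#'                           bounds = rbind(c(0, 1)), seed = 1)
#' opt$par  # 0.3
maximize_surrogate <- function(predict_fn, bounds, n_starts = 64L, seed = 1L) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- as.matrix(bounds)
  k <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    abort("Bounds must be finite with low < high in every dimension.")
  }
  f <- function(x) as.numeric(predict_fn(x))

  U <- withr_seed(seed, lhs::randomLHS(as.integer(n_starts), k))
  starts <- sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)

  best_par <- NULL
  best_val <- -Inf
  recs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    x0 <- starts[s, ]
    v0 <- tryCatch(f(x0), error = function(e) NaN)
    if (!is.finite(v0)) {
      recs[[s]] <- tibble::tibble(start = s, value = NA_real_, skipped = TRUE)
      next
    }
    if (v0 > best_val) { best_val <- v0; best_par <- x0 }
    res <- tryCatch(
      optim(x0, fn = function(x) -f(x), method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(factr = 1e2, pgtol = 1e-10, maxit = 500)),
      error = function(e) NULL
    )
    val <- if (is.null(res)) v0 else -res$value
    if (!is.null(res) && is.finite(val) && val > best_val) {
      best_val <- val
      best_par <- pmin(pmax(res$par, lo), hi)
    }
    recs[[s]] <- tibble::tibble(start = s, value = val, skipped = FALSE)
  }
  if (is.null(best_par)) abort("Objective was non-finite at every start.")
  structure(
    list(par = best_par, value = best_val,
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         starts = dplyr::bind_rows(recs)),
    class = "optimum_result"
  )
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("Surrogate maximum %.4f over %d starts\n", x$value, x$n_starts))
  cat("at:", paste(signif(x$par, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Default practical operating resolutions
#'
#' Resolutions that an operator can actually set: 1 min for times, 0.05
#' mol/L for alkali concentration, 1 mL/g for the liquid-solid ratio, 5 W
#' for ultrasonic power, 0.5 degC for temperature.
#'
#' @return Named numeric vector keyed by [crp_factors()] names.
#' @export
crp_resolutions <- function() {
  c(soak_time = 1, naoh = 0.05, sonic_time = 1, ls_ratio = 1,
    power = 5, temp = 0.5)
}

#' Snap an optimum to practical operating settings
#'
#' Rounds each factor's actual value to the nearest multiple of its
#' practical resolution, ties rounding half away from zero.
#'
#' @param actual Named or ordered numeric vector of actual-unit settings.
#' @param resolutions Positive resolutions, same order/names as `actual`.
#' @return Numeric vector of snapped settings.
#' @export
#' @examples
#' round_to_practice(c(35.05, 137.86, 0.55, 25.9, 325.4, 56.35),
#'                   c(1, 1, 0.05, 1, 5, 0.5))
round_to_practice <- function(actual, resolutions) {
  if (any(resolutions <= 0)) abort("Resolutions must be positive.")
  if (length(actual) != length(resolutions)) {
    abort("`actual` and `resolutions` lengths differ.")
  }
  snapped <- resolutions * round_half_up(actual / resolutions, 0)
  # clean up floating error at the reported precision
  dec <- pmax(0, ceiling(-log10(resolutions)) + 1)
  round(snapped, dec + 6)
}

#' Maximize predicted yield over the design region
#'
#' Wraps [maximize_surrogate()] for a fitted surrogate (`svr_fit` or
#' `rsm_fit`) over the coded design box, reports the optimum in coded and
#' actual units, and snaps it to practical operating resolutions.
#'
#' @param model An `svr_fit` or `rsm_fit`.
#' @param factors Factor table; default [crp_factors()].
#' @param region `"factorial"` (coded `[-1, 1]`, default) or `"axial"`
#'   (coded `[-alpha, alpha]`).
#' @param alpha Axial distance used when `region = "axial"`.
#' @param resolutions Practical resolutions; default [crp_resolutions()].
#' @param n_starts,seed Passed to [maximize_surrogate()].
#'
#' @return A list of class `yield_optimum`: `coded`, `actual`, `predicted`,
#'   `practical` (snapped actual settings), `predicted_practical`,
#'   `surrogate` label, and the underlying `optimum_result`.
#' @export
optimize_yield <- function(model, factors = crp_factors(),
                           region = c("factorial", "axial"),
                           alpha = practical_alpha(nrow(factors)),
                           resolutions = crp_resolutions(),
                           n_starts = 64L, seed = 1L) {
  region <- match.arg(region)
  k <- nrow(factors)
  r <- if (region == "factorial") 1 else alpha
  bounds <- cbind(rep(-r, k), rep(r, k))

  predict_coded <- function(coded) {
    coded <- matrix(coded, nrow = 1L)
    if (inherits(model, "rsm_fit")) {
      predict(model, coded)
    } else {
      actual <- coded_to_actual(factors, coded)
      Xs <- if (is.null(model$scaler)) actual else minmax_apply(actual, model$scaler)
      predict(model, Xs)
    }
  }

  opt <- maximize_surrogate(predict_coded, bounds, n_starts = n_starts,
                            seed = seed)
  actual <- drop(coded_to_actual(factors, opt$par))
  practical <- round_to_practice(actual, resolutions[factors$name])
  coded_prac <- drop(actual_to_coded(factors, practical))
  structure(
    list(
      coded = setNames(opt$par, factors$name),
      actual = setNames(actual, factors$name),
      predicted = opt$value,
      practical = setNames(practical, factors$name),
      predicted_practical = as.numeric(predict_coded(coded_prac)),
      surrogate = class(model)[1],
      region = region,
      result = opt
    ),
    class = "yield_optimum"
  )
}

#' @export
print.yield_optimum <- function(x, ...) {
  cat(sprintf("Predicted yield maximum %.2f%% (%s surrogate, %s region)\n",
              x$predicted, x$surrogate, x$region))
  tbl <- tibble::tibble(factor = names(x$actual),
                        optimum = unname(x$actual),
                        practical = unname(x$practical))
  print(tbl)
  cat(sprintf("Predicted yield at practical settings: %.2f%%\n",
              x$predicted_practical))
  invisible(x)
}

#' @export
#' @method tidy yield_optimum
tidy.yield_optimum <- function(x, ...) {
  tibble::tibble(
    factor = names(x$actual),
    coded = unname(x$coded),
    actual = unname(x$actual),
    practical = unname(x$practical)
  )
}
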