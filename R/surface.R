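#' Specify a second-order response surface in coded units
#'
#' The surface is the full quadratic polynomial
#' `y = b0 + sum_i b_i x_i + sum_{i<j} b_ij x_i x_j + sum_i b_ii x_i^2`
#' evaluated at coded factor levels, plus optional i.i.d. Gaussian noise with
#' standard deviation `noise_sd` (in yield percentage points).
#'
#' @param intercept Intercept `b0`.
#' @param linear Length-`k` vector of linear coefficients.
#' @param interaction Length-`choose(k, 2)` vector of two-factor interaction
#'   coefficients in upper-triangle order (12, 13, ..., 1k, 23, ...).
#' @param quadratic Length-`k` vector of pure quadratic coefficients.
#' @param noise_sd Response noise standard deviation (>= 0).
#'
#' @return A list of class `surface_spec`.
#' @export
surface_spec <- function(intercept, linear, interaction, quadratic,
                         noise_sd = 0) {
  k <- length(linear)
  if (length(quadratic) != k) abort("`quadratic` must match `linear` in length.")
  if (length(interaction) != choose(k, 2)) {
    abort(sprintf("`interaction` must have choose(%d, 2) = %d entries.",
                  k, choose(k, 2)))
  }
  if (!is.finite(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(
      intercept = as.numeric(intercept), linear = as.numeric(linear),
      interaction = as.numeric(interaction), quadratic = as.numeric(quadratic),
      noise_sd = as.numeric(noise_sd), k = k
    ),
    class = "surface_spec"
  )
}

#' Published fitted yield surface for ultrasonic-assisted extraction
#'
#' The fitted quadratic model of extraction yield (%) in coded units over the
#' six process factors of [crp_factors()], as reported by the source study,
#' used in this package as the synthetic ground truth. The default noise
#' standard deviation `sqrt(0.4023) = 0.6343` reproduces the study's
#' pure-error mean square over the ten center replicates.
#'
#' The printed soaking-time-by-power interaction coefficient (0.780) is
#' inconsistent with its own ANOVA sum of squares (0.3891 = 0.078^2 * 64 on
#' the 64-corner design); `variant = "corrected"` (default) stores 0.0780,
#' `variant = "as_printed"` keeps 0.780.
#'
#' @param variant `"corrected"` or `"as_printed"` (see Details).
#' @param noise_sd Noise standard deviation in yield points.
#' @return A [surface_spec()] for `k = 6`.
#' @export
#' @examples
#' s <- crp_yield_surface()
#' eval_surface(s, rep(0, 6))  # 19.33 at the center point
crp_yield_surface <- function(variant = c("corrected", "as_printed"),
                              noise_sd = sqrt(0.4023)) {
  variant <- match.arg(variant)
  b15 <- if (variant == "corrected") 0.0780 else 0.780
  surface_spec(
    intercept = 19.33,
    linear = c(0.3460, 0.1802, 0.5011, 0.4286, 0.2081, -0.2556),
    interaction = c(
      0.0886, -0.0067, 0.0236, b15, -0.1083,   # 12 13 14 15 16
      -0.0111, 0.0817, 0.0405, -0.0402,        # 23 24 25 26
      -0.2873, -0.1011, -0.1967,               # 34 35 36
      -0.0283, 0.2186,                         # 45 46
      -0.0289                                  # 56
    ),
    quadratic = c(-0.769, -0.2811, -1.64, -1.13, -0.2342, -0.0627),
    noise_sd = noise_sd
  )
}

# Expand coded rows into the full quadratic model basis (no intercept):
# linear terms, upper-triangle pairwise products, squares.
quad_basis <- function(coded) {
  coded <- as.matrix(coded)
  k <- ncol(coded)
  pairs <- utils::combn(k, 2)
  inter <- coded[, pairs[1, ], drop = FALSE] * coded[, pairs[2, ], drop = FALSE]
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  colnames(inter) <- paste0(nm[pairs[1, ]], ":", nm[pairs[2, ]])
  sq <- coded^2
  colnames(sq) <- paste0(nm, "^2")
  cbind(coded, inter, sq)
}

#' Evaluate a quadratic surface at coded points
#'
#' @param spec A [surface_spec()].
#' @param coded Coded levels: vector of length `k` or an `n x k` matrix.
#' @return Numeric vector of noiseless surface values.
#' @export
eval_surface <- function(spec, coded) {
  stopifnot(inherits(spec, "surface_spec"))
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
  if (ncol(coded) != spec$k) {
    abort(sprintf("`coded` must have %d columns.", spec$k))
  }
  B <- quad_basis(coded)
  drop(spec$intercept +
         B %*% c(spec$linear, spec$interaction, spec$quadratic))
}

#' Simulate yield responses over a design
#'
#' Draws `yield_pct = surface + N(0, noise_sd^2)` independently per run,
#' reproducibly under `seed`. This emulates the structure the downstream
#' analysis assumes: a smooth quadratic truth plus homoscedastic replicate
#' noise calibrated to the study's pure-error mean square.
#'
#' @param design A [ccd_design()] tibble (coded columns are used).
#' @param spec A [surface_spec()]; defaults to [crp_yield_surface()].
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Optional override of `spec$noise_sd`.
#'
#' @return `design` with a `yield_pct` column appended.
#' @export
#' @examples
#' des <- ccd_design(crp_factors(), n_center = 10, seed = 1)
#' dat <- simulate_yield(des, seed = 7)
#' dplyr::summarise(dat, mean = mean(yield_pct))
simulate_yield <- function(design, spec = crp_yield_surface(), seed = 1L,
                           noise_sd = NULL) {
  coded <- design_matrix(design, "coded")
  if (ncol(coded) != spec$k) abort("Design and surface dimensions differ.")
  sdv <- if (is.null(noise_sd)) spec$noise_sd else noise_sd
  mu <- eval_surface(spec, coded)
  eps <- withr_seed(seed, rnorm(nrow(coded), 0, sdv))
  out <- dplyr::mutate(design, yield_pct = mu + eps)
  attr(out, "surface") <- spec
  attr(out, "noise_seed") <- as.integer(seed)
  out
}
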