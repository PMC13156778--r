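#' Permutation feature importance
#'
#' `PI_j = (RMSE_j - RMSE_0) / RMSE_0`: the relative RMSE increase after
#' randomly permuting column `j`, averaged over `n_rep` seeded permutations.
#'
#' @param model A fitted model with a `predict` method accepting a feature
#'   matrix on the model's input scale (e.g. an `svr_fit`).
#' @param X Feature matrix on the model's input scale.
#' @param y Observed responses.
#' @param n_rep Number of permutation repeats (default 30).
#' @param seed Integer seed.
#' @return Tibble with `feature` and `pi`.
#' @export
permutation_importance <- function(model, X, y, n_rep = 30L, seed = 1L) {
  X <- as.matrix(X)
  base_rmse <- sqrt(mean((y - predict(model, X))^2))
  if (base_rmse == 0) abort("Baseline RMSE is zero; permutation importance undefined.")
  k <- ncol(X)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  pi_j <- withr_seed(seed, {
    vapply(seq_len(k), function(j) {
      reps <- vapply(seq_len(n_rep), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        sqrt(mean((y - predict(model, Xp))^2))
      }, numeric(1))
      (mean(reps) - base_rmse) / base_rmse
    }, numeric(1))
  })
  tibble::tibble(feature = nms, pi = pi_j)
}

#' Partial-dependence curves and their dynamic ranges
#'
#' `partial_dependence()` averages model predictions over the observed rows
#' while feature `j` sweeps a grid across its observed range (the empirical
#' marginalization of all other features). `pd_ranges()` summarizes each
#' curve by its dynamic range normalized across features
#' (`PDR_j = range_j / sum(range_m)`).
#'
#' @inheritParams permutation_importance
#' @param grid_size Grid points per feature (default 50).
#' @return `partial_dependence()`: long tibble `feature`, `value`
#'   (grid point on the input scale), `pd`. `pd_ranges()`: tibble `feature`,
#'   `range`, `pdr`.
#' @export
partial_dependence <- function(model, X, grid_size = 50L) {
  X <- as.matrix(X)
  k <- ncol(X)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  purrr::map_dfr(seq_len(k), function(j) {
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi <= lo) {
      warn(sprintf("Feature '%s' is constant; partial dependence is a point.", nms[j]))
      grid <- lo
    } else {
      grid <- seq(lo, hi, length.out = grid_size)
    }
    pd <- vapply(grid, function(v) {
      Xg <- X
      Xg[, j] <- v
      mean(predict(model, Xg))
    }, numeric(1))
    tibble::tibble(feature = nms[j], value = grid, pd = pd)
  })
}

#' @rdname partial_dependence
#' @param curves Output of `partial_dependence()`.
#' @export
pd_ranges <- function(curves) {
  out <- curves |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(range = max(.data$pd) - min(.data$pd), .groups = "drop")
  tot <- sum(out$range)
  if (tot <= 0) {
    warn("All partial-dependence curves are flat; reporting uniform PDR.")
    out$pdr <- 1 / nrow(out)
  } else {
    out$pdr <- out$range / tot
  }
  # preserve the feature order of the curves
  out[match(unique(curves$feature), out$feature), ]
}

#' Support-vector contribution scores
#'
#' `SV_j = sum_{i in SV} |beta_i| x_ij / sum_m sum_{i in SV} |beta_i| x_im`:
#' each feature's share of absolute-dual-coefficient-weighted coordinate
#' mass over the support vectors, on the `[0, 1]` scaled feature space.
#' Scores sum to one by construction.
#'
#' @param model An `svr_fit` with at least one support vector.
#' @return Tibble with `feature` and `sv`.
#' @export
sv_contribution <- function(model) {
  stopifnot(inherits(model, "svr_fit"))
  sv <- model$support
  if (length(sv) == 0L) abort("Model has no support vectors.")
  w <- abs(model$beta[sv])
  Xsv <- model$X[sv, , drop = FALSE]
  raw <- drop(w %*% Xsv)
  nms <- model$features
  if (is.null(nms)) nms <- paste0("x", seq_along(raw))
  tibble::tibble(feature = nms, sv = raw / sum(raw))
}

minmax01 <- function(x) {
  r <- max(x) - min(x)
  if (r <= 0) {
    warn("Degenerate (all-equal) score vector; using uniform scores.")
    return(rep(1 / length(x), length(x)))
  }
  (x - min(x)) / r
}

#' Fuse importance scores by weighted averaging
#'
#' Min-max normalizes each score vector to `[0, 1]` across features, then
#' combines them with weights (default 0.50 permutation, 0.25
#' partial-dependence range, 0.25 support-vector contribution) and assigns
#' dense descending ranks.
#'
#' @param pi_scores,pdr_scores,sv_scores Equal-length numeric score vectors.
#' @param features Feature names.
#' @param weights Length-3 nonnegative weights summing to 1.
#' @return Tibble of class `importance_report`: `feature`, `pi`, `pdr`,
#'   `sv`, normalized columns, `fused`, `rank`.
#' @export
#' @examples
#' fuse_importance(c(0, 1), c(1, 0), c(1, 0), features = c("a", "b"))
fuse_importance <- function(pi_scores, pdr_scores, sv_scores,
                            features = NULL,
                            weights = c(0.50, 0.25, 0.25)) {
  k <- length(pi_scores)
  if (length(pdr_scores) != k || length(sv_scores) != k) {
    abort("Score vectors must have equal length.")
  }
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be three nonnegative values summing to 1.")
  }
  if (is.null(features)) features <- paste0("x", seq_len(k))
  npi <- minmax01(pi_scores)
  npdr <- minmax01(pdr_scores)
  nsv <- minmax01(sv_scores)
  fused <- weights[1] * npi + weights[2] * npdr + weights[3] * nsv
  out <- tibble::tibble(
    feature = features, pi = pi_scores, pdr = pdr_scores, sv = sv_scores,
    pi_norm = npi, pdr_norm = npdr, sv_norm = nsv,
    fused = fused,
    rank = dplyr::dense_rank(dplyr::desc(fused))
  )
  attr(out, "weights") <- weights
  class(out) <- c("importance_report", class(out))
  out
}

#' Tri-metric feature importance for an SVR model
#'
#' Runs the full importance procedure: permutation importance on the scaled
#' training data, partial-dependence dynamic ranges, support-vector
#' contribution, and weighted fusion.
#'
#' @param model An `svr_fit`.
#' @param y Observed responses for the training rows (defaults to the
#'   responses stored in the model).
#' @param n_rep Permutation repeats.
#' @param seed Integer seed.
#' @param grid_size Partial-dependence grid size.
#' @param weights Fusion weights (PI, PDR, SV).
#' @return An `importance_report` tibble (see [fuse_importance()]) with the
#'   PD curves attached as attribute `"pd_curves"`.
#' @export
#' @examples
#' dat <- simulate_yield(ccd_design(crp_factors(), n_center = 10, seed = 1), seed = 2)
#' fit <- fit_svr(dat, C = 10, gamma = 1, epsilon = 0.01)
#' feature_importance(fit, n_rep = 5, seed = 3)
feature_importance <- function(model, y = model$y, n_rep = 30L, seed = 1L,
                               grid_size = 50L,
                               weights = c(0.50, 0.25, 0.25)) {
  stopifnot(inherits(model, "svr_fit"))
  X <- model$X
  colnames(X) <- model$features
  pi_tbl <- permutation_importance(model, X, y, n_rep = n_rep, seed = seed)
  curves <- partial_dependence(model, X, grid_size = grid_size)
  pdr_tbl <- pd_ranges(curves)
  sv_tbl <- sv_contribution(model)
  out <- fuse_importance(pi_tbl$pi, pdr_tbl$pdr, sv_tbl$sv,
                         features = pi_tbl$feature, weights = weights)
  attr(out, "pd_curves") <- curves
  out
}
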