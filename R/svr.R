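#' Gaussian radial basis kernel
#'
#' `K(u, v) = exp(-gamma * ||u - v||^2)`, with `gamma = 1 / (2 * delta^2)`
#' controlling the kernel width.
#'
#' @param u,v Numeric vectors of equal length, or matrices with matching
#'   column counts (rows are points).
#' @param gamma Positive kernel width parameter.
#' @return Kernel value(s): a scalar for vector inputs, otherwise the
#'   cross-kernel matrix.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1)  # exp(-1)
rbf_kernel <- function(u, v, gamma) {
  if (gamma <= 0) abort("`gamma` must be positive.")
  um <- if (is.null(dim(u))) matrix(u, nrow = 1L) else as.matrix(u)
  vm <- if (is.null(dim(v))) matrix(v, nrow = 1L) else as.matrix(v)
  if (ncol(um) != ncol(vm)) abort("`u` and `v` must have the same dimension.")
  K <- rbf_gram_cpp(um, vm, gamma)
  if (is.null(dim(u)) && is.null(dim(v))) drop(K) else K
}

#' Fit epsilon-insensitive support vector regression
#'
#' Trains an RBF-kernel epsilon-SVR by solving the dual quadratic program
#' (box constraints `[-C, C]` on the net dual coefficients
#' `beta_i = alpha_i - alpha_i*`, equality `sum(beta) = 0`) with a
#' maximal-violating-pair SMO sweep; each pair subproblem is solved exactly.
#' The bias is recovered from the KKT conditions, averaged over free support
#' vectors. Features are min-max scaled to `[0, 1]` internally by default so
#' the kernel treats all factors on a common scale.
#'
#' @param data Data frame containing the feature and response columns, or a
#'   numeric feature matrix (then `y` must be given).
#' @param response Response column name (default `"yield_pct"`).
#' @param features Character vector of feature column names; defaults to the
#'   `actual_*` design columns.
#' @param y Response vector when `data` is a matrix.
#' @param C Box penalty (> 0).
#' @param gamma RBF width (> 0).
#' @param epsilon Insensitive-tube half width (>= 0).
#' @param scale Min-max scale features to `[0, 1]`? Default `TRUE`. Set to
#'   `FALSE` when the inputs are already on the unit scale.
#' @param tol Duality-gap convergence tolerance.
#' @param max_iter Maximum SMO pair updates before aborting.
#'
#' @return An object of class `svr_fit` with elements `beta` (net dual
#'   coefficients), `b` (bias), `support` (indices with `|beta| > 1e-8 * C`),
#'   `X` (scaled training features), `scaler`, hyperparameters, and solver
#'   diagnostics (`objective`, `gap`, `iterations`).
#' @export
#' @examples
#' dat <- simulate_yield(ccd_design(crp_factors(), n_center = 10, seed = 1), seed = 2)
#' fit <- fit_svr(dat, C = 10, gamma = 1, epsilon = 0.01)
#' fit
fit_svr <- function(data, response = "yield_pct", features = NULL, y = NULL,
                    C = 10, gamma = 1, epsilon = 0.01, scale = TRUE,
                    tol = 1e-6, max_iter = 1e6L) {
  if (C <= 0 || gamma <= 0 || epsilon < 0) {
    abort("Require C > 0, gamma > 0, epsilon >= 0.")
  }
  if (is.data.frame(data)) {
    if (is.null(features)) {
      features <- grep("^actual_", names(data), value = TRUE)
      if (length(features) == 0L) {
        features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                            response)
      }
    }
    X <- as.matrix(data[features])
    y <- data[[response]]
  } else {
    X <- as.matrix(data)
    if (is.null(y)) abort("Supply `y` when `data` is a matrix.")
    features <- colnames(X)
  }
  n <- length(y)
  if (n < 2L) abort("Need at least two training points.")

  scaler <- NULL
  Xs <- X
  if (scale) {
    scaler <- minmax_fit(X)
    Xs <- minmax_apply(X, scaler)
  }

  K <- rbf_gram_cpp(Xs, Xs, gamma)
  sol <- smo_svr_cpp(K, as.numeric(y), C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged) {
    # slow tail convergence (ill-conditioned Gram at wide kernels): finish
    # with an exact active-set solve of the KKT system
    pol <- svr_polish(K, as.numeric(y), C, epsilon, sol$beta, tol)
    if (!pol$converged) {
      abort(sprintf(
        "SVR dual solver did not converge (final duality gap %.3e).",
        pol$gap))
    }
    sol$beta <- pol$beta
    sol$gap <- pol$gap
    sol$b <- pol$b
    sol$objective <- pol$dual
    sol$converged <- TRUE
  }
  sv_tol <- 1e-8 * C
  support <- which(abs(sol$beta) > sv_tol)

  structure(
    list(
      beta = sol$beta, b = sol$b, support = support,
      X = Xs, y = as.numeric(y), scaler = scaler, features = features,
      C = C, gamma = gamma, epsilon = epsilon,
      objective = sol$objective, gap = sol$gap, iterations = sol$iterations
    ),
    class = "svr_fit"
  )
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf(
    "epsilon-SVR (RBF): n = %d, C = %g, gamma = %g, epsilon = %g\n",
    length(x$y), x$C, x$gamma, x$epsilon))
  cat(sprintf("%d support vectors (%.0f%%), duality gap %.2e\n",
              length(x$support), 100 * length(x$support) / length(x$y), x$gap))
  invisible(x)
}

#' Predict from an epsilon-SVR fit
#'
#' Evaluates the kernel expansion `sum_i beta_i K(x, x_i) + b` over the
#' support vectors. Data-frame input is passed through the model's stored
#' min-max scaler; matrix input is assumed already scaled and a warning is
#' raised when values fall well outside `[0, 1]`.
#'
#' @param object An `svr_fit`.
#' @param new_data Data frame with the model's feature columns, or a numeric
#'   matrix on the scaled `[0, 1]` feature scale. `NULL` returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.svr_fit <- function(object, new_data = NULL, ...) {
  if (is.null(new_data)) {
    Xs <- object$X
  } else if (is.data.frame(new_data)) {
    X <- as.matrix(new_data[object$features])
    Xs <- if (is.null(object$scaler)) X else minmax_apply(X, object$scaler)
  } else {
    Xs <- as.matrix(new_data)
    if (is.null(dim(new_data))) Xs <- matrix(as.numeric(new_data), nrow = 1L)
    if (any(Xs < -0.1 | Xs > 1.1)) {
      warn("Matrix input to predict.svr_fit() looks unscaled; values outside [-0.1, 1.1].")
    }
  }
  if (ncol(Xs) != ncol(object$X)) {
    abort(sprintf("Expected %d feature columns.", ncol(object$X)))
  }
  sv <- object$support
  if (length(sv) == 0L) return(rep(object$b, nrow(Xs)))
  K <- rbf_gram_cpp(Xs, object$X[sv, , drop = FALSE], object$gamma)
  drop(K %*% object$beta[sv]) + object$b
}

#' @export
#' @method tidy svr_fit
tidy.svr_fit <- function(x, ...) {
  tibble::tibble(
    index = x$support,
    dual_coef = x$beta[x$support],
    at_bound = abs(abs(x$beta[x$support]) - x$C) < 1e-8 * x$C
  )
}

#' @export
#' @method glance svr_fit
glance.svr_fit <- function(x, ...) {
  m <- regression_metrics(x$y, predict(x))
  tibble::tibble(
    n = length(x$y), n_support = length(x$support),
    C = x$C, gamma = x$gamma, epsilon = x$epsilon,
    train.r.squared = m$r.squared, train.rmse = m$rmse,
    dual.objective = x$objective, duality.gap = x$gap
  )
}

# Duality gap of an SVR dual iterate, with the bias chosen to minimize the
# primal exactly (the optimum of the piecewise-linear slack sum sits at a
# breakpoint r_i +/- epsilon).
svr_dual_gap <- function(K, y, C, eps, beta, f = drop(K %*% beta)) {
  dual <- sum(y * beta) - eps * sum(abs(beta)) - 0.5 * sum(beta * f)
  r <- y - f
  bp <- c(r - eps, r + eps)
  slack <- vapply(bp, function(b) sum(pmax(abs(r - b) - eps, 0)), numeric(1))
  best <- min(slack)
  flat <- bp[slack <= best + 1e-12 * (1 + best)]
  list(gap = 0.5 * sum(beta * f) + C * best - dual,
       b = (min(flat) + max(flat)) / 2, dual = dual)
}

# Active-set refinement of an SVR dual iterate. Fixes a sign pattern for the
# free coefficients, solves the equality-constrained KKT system exactly
# (free residuals pinned at +/- epsilon), demotes box violators, and accepts
# the candidate only if the dual improves. Quadratic tail convergence where
# SMO zig-zags.
svr_polish <- function(K, y, C, eps, beta, tol, max_pass = 50L) {
  n <- length(y)
  svtol <- 1e-9 * C
  for (pass in seq_len(max_pass)) {
    f <- drop(K %*% beta)
    gp <- svr_dual_gap(K, y, C, eps, beta, f)
    if (gp$gap < tol) {
      return(list(beta = beta, converged = TRUE, gap = gp$gap, b = gp$b,
                  dual = gp$dual))
    }
    r0 <- y - f - gp$b
    free <- abs(beta) > svtol & abs(beta) < C - svtol
    sgn <- sign(beta)
    at_up <- beta >= C - svtol
    at_lo <- beta <= -C + svtol
    zero <- !free & !at_up & !at_lo
    pz <- zero & abs(r0) > eps
    free[pz] <- TRUE
    sgn[pz] <- sign(r0[pz])
    pu <- at_up & (r0 < eps)
    free[pu] <- TRUE
    sgn[pu] <- 1
    pl <- at_lo & (r0 > -eps)
    free[pl] <- TRUE
    sgn[pl] <- -1
    if (!any(free)) break

    nb <- NULL
    for (inner in seq_len(n)) {
      Fi <- which(free)
      fixed <- beta
      fixed[Fi] <- 0
      M <- rbind(cbind(K[Fi, Fi, drop = FALSE], 1),
                 c(rep(1, length(Fi)), 0))
      rhs <- c(y[Fi] - sgn[Fi] * eps - drop(K[Fi, , drop = FALSE] %*% fixed),
               -sum(fixed))
      sol <- tryCatch(solve(M, rhs), error = function(e) {
        solve(M + diag(1e-10, nrow(M)), rhs)
      })
      bF <- sol[seq_along(Fi)]
      lo_viol <- -(sgn[Fi] * bF)
      hi_viol <- sgn[Fi] * bF - C
      worst <- max(c(lo_viol, hi_viol))
      if (worst <= 1e-12 * max(1, C)) {
        nb <- beta
        nb[-Fi] <- beta[-Fi]
        nb[Fi] <- bF
        break
      }
      w <- which.max(pmax(lo_viol, hi_viol))
      i <- Fi[w]
      beta[i] <- if (lo_viol[w] >= hi_viol[w]) 0 else sgn[i] * C
      free[i] <- FALSE
      at_up[i] <- beta[i] >= C - svtol
      at_lo[i] <- beta[i] <= -C + svtol
    }
    if (is.null(nb)) break

    # accept only dual improvement; backtrack along the feasible segment
    d0 <- gp$dual
    step <- 1
    improved <- FALSE
    for (ls in 1:20) {
      cand <- beta + step * (nb - beta)
      dc <- svr_dual_gap(K, y, C, eps, cand)$dual
      if (dc > d0 + 1e-14 * abs(d0)) {
        beta <- cand
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  gp <- svr_dual_gap(K, y, C, eps, beta)
  list(beta = beta, converged = gp$gap < tol, gap = gp$gap, b = gp$b,
       dual = gp$dual)
}

#' Default hyperparameter grid for SVR tuning
#'
#' The 100-combination grid searched per fold: five penalties, five kernel
#' widths and four tube widths.
#'
#' @return A tibble with columns `C`, `gamma`, `epsilon` (100 rows).
#' @export
svr_default_grid <- function() {
  tidyr::expand_grid(
    C = c(0.1, 1, 10, 100, 1000),
    gamma = c(0.001, 0.01, 0.1, 1, 10),
    epsilon = c(0.001, 0.01, 0.1, 1.0)
  )
}

seeded_folds <- function(n, k, seed) {
  ord <- withr_seed(seed, sample.int(n))
  split(ord, rep_len(seq_len(k), n))
}

#' Nested cross-validated grid search for SVR hyperparameters
#'
#' Outer k-fold cross-validation estimates generalization; within each outer
#' training set, an inner k-fold grid search picks the `(C, gamma, epsilon)`
#' combination minimizing mean inner RMSE (ties broken toward smaller `C`,
#' then larger `epsilon`, i.e. the flatter model). The outer model is refit
#' at each fold's winner and scored on the held-out outer fold. Final
#' hyperparameters aggregate the fold winners — geometric mean for `C` and
#' `gamma`, arithmetic mean for `epsilon` — snapped to the nearest grid point
#' (log-scale nearness for `C` and `gamma`).
#'
#' @inheritParams fit_svr
#' @param grid Hyperparameter tibble; default [svr_default_grid()].
#' @param k_folds Folds for both loops (default 5).
#' @param seed Integer seed controlling both fold assignments.
#' @param tune_tol Duality-gap tolerance for the throwaway inner-grid fits
#'   (looser than `tol`; ranking fold RMSEs does not need tight gaps).
#' @param tol Duality-gap tolerance for outer refits and the final model.
#'
#' @return An object of class `svr_cv`: list with `outer` (per-fold tibble of
#'   chosen hyperparameters and test metrics), `final` (aggregated
#'   hyperparameters), `inner` (per-fold grid RMSE surface, long format), and
#'   `model` (an `svr_fit` refit on all data at the final hyperparameters).
#' @export
#' @examples
#' \donttest{
#' dat <- simulate_yield(ccd_design(crp_factors(), n_center = 10, seed = 1), seed = 2)
#' cv <- svr_tune_nested(dat, seed = 3)
#' glance(cv)
#' }
svr_tune_nested <- function(data, response = "yield_pct", features = NULL,
                            grid = svr_default_grid(), k_folds = 5L,
                            seed = 1L, scale = TRUE, tune_tol = 1e-3,
                            tol = 1e-6) {
  if (nrow(grid) == 0L) abort("Hyperparameter grid is empty.")
  if (is.data.frame(data) && is.null(features)) {
    features <- grep("^actual_", names(data), value = TRUE)
  }
  X <- as.matrix(data[features])
  y <- data[[response]]
  n <- length(y)
  if (n < 2L * k_folds) abort("Need at least 2 observations per fold.")

  outer_folds <- seeded_folds(n, k_folds, seed)
  inner_records <- list()
  outer_records <- list()

  for (fo in seq_along(outer_folds)) {
    test_idx <- outer_folds[[fo]]
    train_idx <- setdiff(seq_len(n), test_idx)
    Xtr <- X[train_idx, , drop = FALSE]
    ytr <- y[train_idx]

    inner_folds <- seeded_folds(length(train_idx), k_folds,
                                seed = seed * 1000L + fo)
    rmse_grid <- matrix(NA_real_, nrow = nrow(grid), ncol = k_folds)
    for (fi in seq_len(k_folds)) {
      val <- inner_folds[[fi]]
      fit_i <- setdiff(seq_along(train_idx), val)
      if (length(val) < 1L || length(fit_i) < 2L) abort("Fold with too few samples.")
      for (g in seq_len(nrow(grid))) {
        m <- fit_svr(Xtr[fit_i, , drop = FALSE], y = ytr[fit_i],
                     C = grid$C[g], gamma = grid$gamma[g],
                     epsilon = grid$epsilon[g], scale = scale,
                     tol = tune_tol)
        # held-out rows can fall slightly outside the fold scaler's range;
        # that is expected, so the out-of-range warning is muffled here
        pred <- suppressWarnings(predict(m, if (scale) {
          minmax_apply(Xtr[val, , drop = FALSE], m$scaler)
        } else Xtr[val, , drop = FALSE]))
        rmse_grid[g, fi] <- sqrt(mean((ytr[val] - pred)^2))
      }
    }
    mean_rmse <- rowMeans(rmse_grid)
    # ties toward smaller C, then larger epsilon
    ord <- order(mean_rmse, grid$C, -grid$epsilon)
    best <- ord[1]

    m_best <- fit_svr(Xtr, y = ytr, C = grid$C[best], gamma = grid$gamma[best],
                      epsilon = grid$epsilon[best], scale = scale, tol = tol)
    pred_te <- suppressWarnings(predict(m_best, if (scale) {
      minmax_apply(X[test_idx, , drop = FALSE], m_best$scaler)
    } else X[test_idx, , drop = FALSE]))
    met <- regression_metrics(y[test_idx], pred_te)

    outer_records[[fo]] <- tibble::tibble(
      fold = fo, C = grid$C[best], gamma = grid$gamma[best],
      epsilon = grid$epsilon[best],
      r.squared = met$r.squared, rmse = met$rmse,
      mae = met$mae, mape = met$mape
    )
    inner_records[[fo]] <- dplyr::mutate(grid, fold = fo,
                                         mean_rmse = mean_rmse)
  }

  outer <- dplyr::bind_rows(outer_records)
  snap <- function(x, levels, log_scale = FALSE) {
    d <- if (log_scale) abs(log(levels) - log(x)) else abs(levels - x)
    levels[which.min(d)]
  }
  gm <- function(x) exp(mean(log(x)))
  final <- tibble::tibble(
    C = snap(gm(outer$C), sort(unique(grid$C)), log_scale = TRUE),
    gamma = snap(gm(outer$gamma), sort(unique(grid$gamma)), log_scale = TRUE),
    epsilon = snap(mean(outer$epsilon), sort(unique(grid$epsilon)))
  )

  model <- fit_svr(X, y = y, C = final$C, gamma = final$gamma,
                   epsilon = final$epsilon, scale = scale, tol = tol)
  model$features <- features

  structure(
    list(outer = outer, final = final,
         inner = dplyr::bind_rows(inner_records), model = model,
         k_folds = k_folds, seed = as.integer(seed)),
    class = "svr_cv"
  )
}

#' @export
print.svr_cv <- function(x, ...) {
  cat(sprintf("Nested %d-fold CV over %d grid points\n",
              x$k_folds, nrow(dplyr::distinct(x$inner[c("C", "gamma", "epsilon")]))))
  cat(sprintf("Final: C = %g, gamma = %g, epsilon = %g\n",
              x$final$C, x$final$gamma, x$final$epsilon))
  cat(sprintf("Outer mean R2 = %.4f, mean RMSE = %.4f\n",
              mean(x$outer$r.squared), mean(x$outer$rmse)))
  invisible(x)
}

#' @export
#' @method tidy svr_cv
tidy.svr_cv <- function(x, ...) x$outer

#' @export
#' @method glance svr_cv
glance.svr_cv <- function(x, ...) {
  tibble::tibble(
    mean.r.squared = mean(x$outer$r.squared),
    mean.rmse = mean(x$outer$rmse),
    sd.rmse = sd(x$outer$rmse),
    C = x$final$C, gamma = x$final$gamma, epsilon = x$final$epsilon,
    n_support = length(x$model$support)
  )
}
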