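#' Min-max scaling to the unit interval
#'
#' `minmax_fit()` learns per-column minima and maxima; `minmax_apply()` maps
#' each column through `(x - min) / (max - min)`; `minmax_invert()` undoes the
#' map. Columns with zero range are rejected at fit time because the forward
#' map would be undefined.
#'
#' @param X Numeric matrix or data frame (rows are runs).
#' @param params A `minmax_params` object from `minmax_fit()`.
#' @return `minmax_fit()` returns a `minmax_params` list (`min`, `max`);
#'   the other two return a numeric matrix.
#' @export
#' @examples
#' p <- minmax_fit(cbind(a = c(2, 4, 6)))
#' minmax_apply(cbind(a = c(2, 4, 6)), p)  # 0, 0.5, 1
minmax_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) abort("Need at least two rows to fit a min-max scaler.")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  flat <- which(maxs <= mins)
  if (length(flat) > 0L) {
    nms <- colnames(X)[flat]
    if (is.null(nms)) nms <- as.character(flat)
    abort(paste0("Constant column(s) cannot be min-max scaled: ",
                 paste(nms, collapse = ", ")))
  }
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' @rdname minmax_fit
#' @export
minmax_apply <- function(X, params) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$min, `-`), 2, params$max - params$min, `/`)
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(X, params) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$max - params$min, `*`), 2, params$min, `+`)
}

#' Mahalanobis outlier screen
#'
#' Computes squared Mahalanobis distances from the column means under the
#' unbiased sample covariance and flags rows at or beyond the chi-squared
#' quantile threshold for `k` degrees of freedom (22.46 for `k = 6` at the
#' 0.999 quantile).
#'
#' @param data Data frame or matrix of the columns to screen.
#' @param cols Optional tidy-select of columns (defaults to all numeric).
#' @param quantile Chi-squared quantile defining the flag threshold.
#'
#' @return A tibble with `d2`, logical `outlier`, and attributes `threshold`
#'   and `quantile`.
#' @export
#' @examples
#' X <- matrix(rnorm(600), ncol = 6)
#' scr <- mahalanobis_screen(X)
#' attr(scr, "threshold")  # 22.46
mahalanobis_screen <- function(data, cols = NULL, quantile = 0.999) {
  X <- if (is.data.frame(data)) {
    sel <- if (rlang::quo_is_null(rlang::enquo(cols))) {
      names(data)[vapply(data, is.numeric, logical(1))]
    } else {
      names(tidyr::as_tibble(data) |> dplyr::select({{ cols }}))
    }
    as.matrix(data[sel])
  } else {
    as.matrix(data)
  }
  n <- nrow(X); k <- ncol(X)
  if (n <= k) abort("Need more rows than columns for a nonsingular covariance.")
  S <- cov(X)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(S)) || abs(det(S)) < 1e-300) {
    abort("Sample covariance is singular; consider dropping collinear columns or regularizing.")
  }
  d2 <- mahalanobis(X, colMeans(X), S)
  thr <- qchisq(quantile, df = k)
  out <- tibble::tibble(d2 = d2, outlier = d2 >= thr)
  attr(out, "threshold") <- thr
  attr(out, "quantile") <- quantile
  out
}

#' Stratified train/test split on the response
#'
#' Bins the response into `n_strata` quantile strata and samples a seeded
#' `test_frac` share within each stratum, so both partitions span the yield
#' range. Per-stratum test counts are reconciled with a largest-remainder
#' rule so the overall test size is exactly `round(n * test_frac)`.
#'
#' @param y Numeric response vector.
#' @param test_frac Test fraction in (0, 1); default 0.2.
#' @param n_strata Number of quantile strata; default 5 (quintiles).
#' @param seed Integer seed.
#'
#' @return A tibble with columns `index`, `stratum`, `label`
#'   (`"train"`/`"test"`).
#' @export
#' @examples
#' sp <- stratified_split(rnorm(86), seed = 3)
#' table(sp$label)  # 69 train / 17 test
stratified_split <- function(y, test_frac = 0.2, n_strata = 5L, seed = 1L) {
  n <- length(y)
  if (test_frac <= 0 || test_frac >= 1) abort("`test_frac` must be in (0, 1).")
  if (n < n_strata) abort("Need at least `n_strata` observations.")

  # quantile strata; ties broken by stable order of appearance
  ranks <- rank(y, ties.method = "first")
  stratum <- ceiling(ranks * n_strata / n)

  n_test <- round(n * test_frac)
  sizes <- tabulate(stratum, nbins = n_strata)
  quota <- sizes * test_frac
  take <- floor(quota)
  short <- n_test - sum(take)
  if (short > 0) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(short)]
    take[extra] <- take[extra] + 1L
  } else if (short < 0) {
    drop_ <- order(quota - take)[seq_len(-short)]
    take[drop_] <- pmax(take[drop_] - 1L, 0L)
  }

  label <- rep("train", n)
  withr_seed(seed, {
    for (s in seq_len(n_strata)) {
      idx <- which(stratum == s)
      if (take[s] > 0L && length(idx) > 0L) {
        label[sample(idx, min(take[s], length(idx)))] <- "test"
      }
    }
  })
  tibble::tibble(index = seq_len(n), stratum = as.integer(stratum), label = label)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' on the remaining columns with an intercept. Perfectly collinear columns
#' yield `Inf` rather than an error.
#'
#' @param X Numeric matrix or data frame with at least two columns.
#' @return A tibble with `feature` and `vif`.
#' @export
#' @examples
#' vif_scores(matrix(rnorm(300), ncol = 3))
vif_scores <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (k < 2) abort("Need at least two columns for VIFs.")
  if (n <= k) abort("Need more rows than columns for VIFs.")
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(k))
  v <- vapply(seq_len(k), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(feature = nms, vif = v)
}
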