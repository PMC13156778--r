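#' Regression performance metrics
#'
#' Computes the coefficient of determination, root-mean-square error, mean
#' absolute error and mean absolute percentage error of predictions against
#' observations. MAPE is the mean absolute relative error times 100; it is
#' omitted (`NA`) with a warning when any observation equals zero.
#'
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return A one-row tibble: `r.squared`, `rmse`, `mae`, `mape`, `n`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` lengths differ.")
  n <- length(y)
  if (n < 2L) abort("Need at least two observations.")
  e <- y - y_hat
  ss_res <- sum(e^2)
  ss_tot <- sum((y - mean(y))^2)
  mape <- if (any(y == 0)) {
    warn("Zero observations present; MAPE omitted.")
    NA_real_
  } else {
    mean(abs(e / y)) * 100
  }
  tibble::tibble(
    r.squared = 1 - ss_res / ss_tot,
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    mape = mape,
    n = n
  )
}

#' Generalization gap rule
#'
#' `delta = R2_train - R2_test`, judged acceptable when below 0.10.
#'
#' @param train_r2,test_r2 Training and testing R-squared.
#' @param threshold Acceptability threshold (default 0.10).
#' @return Tibble with `delta_r2` and logical `acceptable`.
#' @export
#' @examples
#' generalization_gap(0.9907, 0.9027)  # 0.0880, acceptable
generalization_gap <- function(train_r2, test_r2, threshold = 0.10) {
  stopifnot(is.finite(train_r2), is.finite(test_r2))
  d <- train_r2 - test_r2
  tibble::tibble(delta_r2 = d, acceptable = d < threshold)
}

#' Paired t-test on absolute prediction errors
#'
#' Two-sided paired t-test comparing `|e1|` against `|e2|`, the standard way
#' to ask whether one model's absolute errors are systematically smaller on
#' the same held-out points.
#'
#' @param e1,e2 Prediction error vectors of equal length (signed errors are
#'   accepted; absolute values are compared).
#' @return Tibble with `statistic`, `df`, `p.value`, `mean_diff`
#'   (`mean(|e1| - |e2|)`). Zero-variance differences yield a degenerate
#'   result (`NA` statistic) with a warning.
#' @export
paired_error_test <- function(e1, e2) {
  if (length(e1) != length(e2)) abort("Error vectors must have equal length.")
  if (length(e1) < 2L) abort("Need at least two pairs.")
  d <- abs(e1) - abs(e2)
  if (sd(d) == 0) {
    warn("Zero-variance differences; paired t-test degenerate.")
    return(tibble::tibble(statistic = NA_real_, df = length(d) - 1L,
                          p.value = if (all(d == 0)) 1 else NA_real_,
                          mean_diff = mean(d)))
  }
  tt <- t.test(abs(e1), abs(e2), paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p.value = tt$p.value, mean_diff = mean(d))
}

# Jarque-Bera normality test on a plain numeric vector.
jarque_bera <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- mean(z^2)
  skew <- mean(z^3) / s2^1.5
  kurt <- mean(z^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  c(statistic = jb, p.value = pchisq(jb, df = 2, lower.tail = FALSE))
}

# Breusch-Pagan test, studentized (Koenker) form: LM = n * R^2 of the
# auxiliary regression of squared residuals on the given regressors.
breusch_pagan <- function(residuals, Z, studentized = TRUE) {
  n <- length(residuals)
  u2 <- residuals^2
  Zm <- cbind(1, as.matrix(Z))
  fit <- lm.fit(Zm, u2)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((u2 - mean(u2))^2)
  df <- ncol(Zm) - 1L
  if (ss_tot <= 0) return(c(statistic = NA_real_, p.value = NA_real_))
  if (studentized) {
    lm_stat <- n * (1 - ss_res / ss_tot)
  } else {
    sigma2 <- mean(u2)
    lm_stat <- (ss_tot - ss_res) / (2 * sigma2^2)
  }
  c(statistic = lm_stat, p.value = pchisq(lm_stat, df = df, lower.tail = FALSE))
}

#' Durbin-Watson statistic
#'
#' `sum(diff(e)^2) / sum(e^2)`; near 2 for serially uncorrelated residuals,
#' approximately `2 * (1 - r1)` for lag-1 autocorrelation `r1`.
#'
#' @param residuals Residual vector in observation order.
#' @return A single number in `[0, 4]`.
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) abort("Need at least two residuals.")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Residual diagnostics battery
#'
#' Normality via Lilliefors (Kolmogorov-Smirnov with estimated parameters),
#' Jarque-Bera and Anderson-Darling; homoscedasticity via Breusch-Pagan in
#' the studentized (Koenker) form regressing squared residuals on the fitted
#' values (optionally also on raw features); independence via the
#' Durbin-Watson statistic.
#'
#' @param residuals Residual vector.
#' @param fitted Fitted values (same length), used as the Breusch-Pagan
#'   regressor.
#' @param X Optional feature matrix appended to the Breusch-Pagan regressors.
#' @param studentized Use the Koenker form of Breusch-Pagan (default `TRUE`).
#' @return A tibble with one row per test: `test`, `statistic`, `p.value`.
#'   Constant residuals yield all-`NA` rows with a warning; `n < 8` triggers
#'   a small-sample warning since the p-values are asymptotic.
#' @export
residual_diagnostics <- function(residuals, fitted, X = NULL,
                                 studentized = TRUE) {
  n <- length(residuals)
  if (length(fitted) != n) abort("`residuals` and `fitted` lengths differ.")
  if (n < 8L) warn("Fewer than 8 residuals; asymptotic p-values are unreliable.")
  if (sd(residuals) == 0) {
    warn("Constant residuals; diagnostics undefined.")
    return(tibble::tibble(
      test = c("lilliefors", "jarque_bera", "anderson_darling",
               "breusch_pagan", "durbin_watson"),
      statistic = NA_real_, p.value = NA_real_
    ))
  }
  lt <- nortest::lillie.test(residuals)
  at <- nortest::ad.test(residuals)
  jb <- jarque_bera(residuals)
  Z <- if (is.null(X)) matrix(fitted, ncol = 1L) else cbind(fitted, as.matrix(X))
  bp <- breusch_pagan(residuals, Z, studentized = studentized)
  tibble::tibble(
    test = c("lilliefors", "jarque_bera", "anderson_darling",
             "breusch_pagan", "durbin_watson"),
    statistic = c(unname(lt$statistic), jb[["statistic"]],
                  unname(at$statistic), bp[["statistic"]],
                  durbin_watson(residuals)),
    p.value = c(lt$p.value, jb[["p.value"]], at$p.value, bp[["p.value"]],
                NA_real_)
  )
}

#' Side-by-side model comparison on a common test set
#'
#' Computes test metrics for two prediction vectors against the same
#' observations, the paired t-test on their absolute errors, and each
#' model's generalization gap.
#'
#' @param y_test Observed test responses.
#' @param pred_a,pred_b Test predictions from models A and B.
#' @param label_a,label_b Model labels.
#' @param train_r2_a,train_r2_b Optional training R-squared values for the
#'   generalization-gap rule.
#' @return A list with `metrics` (two-row tibble), `paired_test`, and
#'   `gaps` (when training R-squared supplied).
#' @export
compare_models <- function(y_test, pred_a, pred_b,
                           label_a = "svr", label_b = "rsm",
                           train_r2_a = NULL, train_r2_b = NULL) {
  ma <- regression_metrics(y_test, pred_a)
  mb <- regression_metrics(y_test, pred_b)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(ma, model = label_a, .before = 1),
    dplyr::mutate(mb, model = label_b, .before = 1)
  )
  pt <- paired_error_test(y_test - pred_a, y_test - pred_b)
  gaps <- NULL
  if (!is.null(train_r2_a) && !is.null(train_r2_b)) {
    gaps <- dplyr::bind_rows(
      dplyr::mutate(generalization_gap(train_r2_a, ma$r.squared),
                    model = label_a, .before = 1),
      dplyr::mutate(generalization_gap(train_r2_b, mb$r.squared),
                    model = label_b, .before = 1)
    )
  }
  list(metrics = metrics, paired_test = pt, gaps = gaps)
}
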