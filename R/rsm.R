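#' Fit a full second-order response-surface model
#'
#' Ordinary least squares on the complete quadratic basis in coded units:
#' intercept, all linear terms, all two-factor interactions and all pure
#' quadratic terms (28 coefficients for six factors). Fitting in coded space
#' keeps the factorial columns orthogonal, so linear and interaction partial
#' sums of squares reduce to `coef^2 * sum(column^2)`.
#'
#' @param data A design tibble with `coded_*` columns (see [ccd_design()])
#'   and a response column.
#' @param response Name of the response column; default `"yield_pct"`.
#'
#' @return An object of class `rsm_fit`: list with the underlying `lm` fit,
#'   a `terms` tibble (term, estimate, std.error, statistic, p.value,
#'   conf.low, conf.high at 95%), the term labels, and the training frame.
#' @export
#' @examples
#' dat <- simulate_yield(ccd_design(crp_factors(), n_center = 10, seed = 1), seed = 2)
#' fit <- fit_rsm(dat)
#' glance(fit)
fit_rsm <- function(data, response = "yield_pct") {
  if (!response %in% names(data)) {
    abort(sprintf("Response column '%s' not found.", response))
  }
  X <- design_matrix(data, "coded")
  y <- data[[response]]
  B <- quad_basis(X)
  p <- ncol(B) + 1L
  n <- length(y)
  if (n <= p) {
    abort(sprintf("Need more than %d runs to fit %d coefficients; got %d.", p, p, n))
  }

  labels <- colnames(B)
  safe <- paste0("t", seq_along(labels))
  dd <- as.data.frame(B)
  names(dd) <- safe
  dd$.y <- y
  fit <- lm(.y ~ ., data = dd)

  if (fit$rank < p) {
    aliased <- labels[is.na(coef(fit))[-1]]
    abort(paste0("Design is rank deficient; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }

  ci <- stats::confint(fit)
  sm <- summary(fit)$coefficients
  terms_tbl <- tibble::tibble(
    term = c("(Intercept)", labels),
    estimate = unname(coef(fit)),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )

  structure(
    list(
      lm = fit, terms = terms_tbl, labels = labels,
      feature_names = colnames(X), coded = X, y = y, n = n, p = p,
      response = response
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Second-order response-surface fit: %d runs, %d coefficients\n",
              x$n, x$p))
  g <- glance(x)
  cat(sprintf("R2 %.4f | adj R2 %.4f | pred R2 %.4f | sigma %.4f\n",
              g$r.squared, g$adj.r.squared, g$pred.r.squared, g$sigma))
  invisible(x)
}

#' Predict from a response-surface fit
#'
#' @param object An `rsm_fit`.
#' @param new_data Tibble with `coded_*` columns, or a coded matrix/vector.
#' @param ... Unused.
#' @return Numeric vector of predicted yields.
#' @export
predict.rsm_fit <- function(object, new_data = NULL, ...) {
  if (is.null(new_data)) return(unname(stats::fitted(object$lm)))
  coded <- if (is.data.frame(new_data) &&
               any(grepl("^coded_", names(new_data)))) {
    design_matrix(new_data, "coded")
  } else if (is.null(dim(new_data))) {
    matrix(as.numeric(new_data), nrow = 1L)
  } else {
    as.matrix(new_data)
  }
  if (ncol(coded) != length(object$feature_names)) {
    abort(sprintf("Expected %d coded columns.", length(object$feature_names)))
  }
  B <- quad_basis(coded)
  drop(cbind(1, B) %*% coef(object$lm))
}

#' @export
#' @method tidy rsm_fit
tidy.rsm_fit <- function(x, ...) x$terms

#' @export
#' @method glance rsm_fit
glance.rsm_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    pred.r.squared = predicted_r2(x),
    sigma = s$sigma,
    statistic = unname(s$fstatistic[1]),
    p.value = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                        lower.tail = FALSE)),
    df.residual = x$lm$df.residual,
    nobs = x$n
  )
}

#' Predicted R-squared from PRESS residuals
#'
#' `1 - PRESS / SS_total` where the PRESS residuals are `e_i / (1 - h_ii)`.
#' Observations with leverage numerically equal to 1 are excluded from PRESS
#' with a warning (their deletion residual is undefined).
#'
#' @param fit An `rsm_fit`.
#' @return A single number, always <= the ordinary R-squared.
#' @export
predicted_r2 <- function(fit) {
  h <- stats::lm.influence(fit$lm, do.coef = FALSE)$hat
  e <- stats::residuals(fit$lm)
  keep <- h < 1 - 1e-10
  if (!all(keep)) {
    warn(sprintf("%d observation(s) with leverage 1 excluded from PRESS.",
                 sum(!keep)))
  }
  press <- sum((e[keep] / (1 - h[keep]))^2)
  ss_tot <- sum((fit$y - mean(fit$y))^2)
  1 - press / ss_tot
}

#' Lack-of-fit F test from sums of squares
#'
#' The mean-square ratio `(SS_lof / df_lof) / (SS_pe / df_pe)` with its
#' upper-tail F p-value; used internally by [rsm_anova()] and applicable
#' directly to any printed ANOVA decomposition.
#'
#' @param ss_lof,df_lof Lack-of-fit sum of squares and degrees of freedom.
#' @param ss_pe,df_pe Pure-error sum of squares and degrees of freedom.
#' @return Tibble with `statistic` and `p.value`.
#' @export
#' @examples
#' lack_of_fit_test(30.70, 49, 3.62, 9)  # F = 1.56
lack_of_fit_test <- function(ss_lof, df_lof, ss_pe, df_pe) {
  stopifnot(df_lof > 0, df_pe > 0, ss_pe > 0)
  f <- (ss_lof / df_lof) / (ss_pe / df_pe)
  tibble::tibble(statistic = f,
                 p.value = pf(f, df_lof, df_pe, lower.tail = FALSE))
}

#' Coefficient of determination from sums of squares
#'
#' @param ss_res Residual sum of squares.
#' @param ss_tot Corrected total sum of squares.
#' @return `1 - ss_res / ss_tot`.
#' @export
#' @examples
#' r_squared_from_ss(34.32, 302.05)  # 0.8864
r_squared_from_ss <- function(ss_res, ss_tot) {
  stopifnot(ss_tot > 0)
  1 - ss_res / ss_tot
}

#' Full ANOVA for a response-surface fit
#'
#' Decomposes the corrected total sum of squares into model and residual,
#' the residual into lack-of-fit (across distinct design points) and pure
#' error (within replicated design points), and reports per-term partial
#' (Type-III) sums of squares `coef^2 / [(X'X)^-1]_jj` with F statistics
#' against the residual mean square. When the design carries no replicated
#' runs the lack-of-fit rows are omitted with a warning.
#'
#' @param fit An `rsm_fit`.
#' @param type `"partial"` (Type-III, default) or `"sequential"` (Type-I).
#'
#' @return A tibble of class `rsm_anova` with columns `term`, `ss`, `df`,
#'   `ms`, `statistic`, `p.value`; rows Model, every model term, Residual,
#'   `Lack of fit`, `Pure error`, `Total (corr.)`. Fit statistics (R2,
#'   adjusted R2, predicted R2) are carried as attributes and via
#'   [glance()] on the fit.
#' @export
#' @examples
#' dat <- simulate_yield(ccd_design(crp_factors(), n_center = 10, seed = 1), seed = 2)
#' rsm_anova(fit_rsm(dat))
rsm_anova <- function(fit, type = c("partial", "sequential")) {
  type <- match.arg(type)
  y <- fit$y
  n <- fit$n
  res <- stats::residuals(fit$lm)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(res^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- fit$p - 1L
  df_res <- n - fit$p
  ms_res <- ss_res / df_res

  if (type == "partial") {
    XtXi <- summary(fit$lm)$cov.unscaled
    b <- coef(fit$lm)
    ss_term <- (b^2 / diag(XtXi))[-1]  # drop intercept
  } else {
    a1 <- stats::anova(fit$lm)
    ss_term <- a1$`Sum Sq`[seq_len(fit$p - 1L)]
  }
  names(ss_term) <- fit$labels

  term_rows <- tibble::tibble(
    term = fit$labels, ss = unname(ss_term), df = 1L,
    ms = unname(ss_term),
    statistic = unname(ss_term) / ms_res,
    p.value = pf(unname(ss_term) / ms_res, 1, df_res, lower.tail = FALSE)
  )

  # pure error: replicate groups share an identical coded row
  key <- apply(round(fit$coded, 10), 1, paste, collapse = "|")
  groups <- split(y, key)
  reps <- groups[vapply(groups, length, integer(1)) > 1L]
  has_pe <- length(reps) > 0L

  lof_rows <- NULL
  if (has_pe) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(vapply(reps, function(g) length(g) - 1L, integer(1)))
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    if (df_lof > 0 && ss_pe > 0) {
      lt <- lack_of_fit_test(ss_lof, df_lof, ss_pe, df_pe)
      lof_rows <- tibble::tibble(
        term = c("Lack of fit", "Pure error"),
        ss = c(ss_lof, ss_pe), df = c(df_lof, df_pe),
        ms = c(ss_lof / df_lof, ss_pe / df_pe),
        statistic = c(lt$statistic, NA_real_),
        p.value = c(lt$p.value, NA_real_)
      )
    }
  } else {
    warn("No replicated design points: lack-of-fit decomposition omitted.")
  }

  f_mod <- (ss_mod / df_mod) / ms_res
  out <- dplyr::bind_rows(
    tibble::tibble(term = "Model", ss = ss_mod, df = df_mod, ms = ss_mod / df_mod,
                   statistic = f_mod,
                   p.value = pf(f_mod, df_mod, df_res, lower.tail = FALSE)),
    term_rows,
    tibble::tibble(term = "Residual", ss = ss_res, df = df_res, ms = ms_res,
                   statistic = NA_real_, p.value = NA_real_),
    lof_rows,
    tibble::tibble(term = "Total (corr.)", ss = ss_tot, df = n - 1L,
                   ms = NA_real_, statistic = NA_real_, p.value = NA_real_)
  )
  r2 <- r_squared_from_ss(ss_res, ss_tot)
  attr(out, "r.squared") <- r2
  attr(out, "adj.r.squared") <- 1 - (1 - r2) * (n - 1) / df_res
  attr(out, "pred.r.squared") <- predicted_r2(fit)
  class(out) <- c("rsm_anova", class(out))
  out
}
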