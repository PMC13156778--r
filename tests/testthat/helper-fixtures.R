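# Shared fixtures, built once per test run.

paper_factors <- crp_factors()
paper_alpha <- practical_alpha(6)
paper_design <- ccd_design(paper_factors, n_center = 10, seed = 101)
paper_surface <- crp_yield_surface()

# noise-free and noisy datasets over the standard design
data_exact <- simulate_yield(paper_design, paper_surface, seed = 1, noise_sd = 0)
data_noisy <- simulate_yield(paper_design, paper_surface, seed = 202)

# flat coefficient vector of the synthetic truth, in model-term order
surface_coefs <- function(spec = paper_surface) {
  c(spec$intercept, spec$linear, spec$interaction, spec$quadratic)
}

# a minimal model wrapper so importance helpers can be exercised on plain
# functions of the feature matrix
fn_model <- function(f) structure(list(f = f), class = "fn_model")
predict.fn_model <- function(object, newdata, ...) {
  apply(as.matrix(newdata), 1, object$f)
}
registerS3method("predict", "fn_model", predict.fn_model,
                 envir = asNamespace("stats"))

# Brute-force dual QP oracle for epsilon-SVR on tiny instances: enumerate
# every KKT sign/bound pattern (zero, +C, -C, free positive, free negative)
# over the n net dual coefficients, solve the resulting linear system, keep
# the feasible pattern with the best dual objective. Exact up to the linear
# solves and fully independent of the package's SMO path.
svr_qp_oracle <- function(X, y, C, gamma, epsilon) {
  n <- length(y)
  stopifnot(n <= 6)
  K <- rbf_kernel(X, X, gamma)
  dual_value <- function(beta) {
    sum(y * beta) - epsilon * sum(abs(beta)) -
      0.5 * drop(t(beta) %*% K %*% beta)
  }
  states <- as.matrix(expand.grid(rep(list(1:5), n)))  # 1=0 2=+C 3=-C 4=F+ 5=F-
  best <- NULL
  for (row in seq_len(nrow(states))) {
    st <- states[row, ]
    beta <- numeric(n)
    beta[st == 2] <- C
    beta[st == 3] <- -C
    Fi <- which(st >= 4)
    sgn <- ifelse(st == 4, 1, -1)
    if (length(Fi) > 0) {
      M <- rbind(cbind(K[Fi, Fi, drop = FALSE], 1),
                 c(rep(1, length(Fi)), 0))
      fixed <- beta
      rhs <- c(y[Fi] - sgn[Fi] * epsilon -
                 drop(K[Fi, , drop = FALSE] %*% fixed), -sum(fixed))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      bF <- sol[seq_along(Fi)]
      b <- sol[length(sol)]
      if (any(sgn[Fi] * bF < -1e-10) || any(sgn[Fi] * bF > C + 1e-10)) next
      beta[Fi] <- bF
    } else {
      if (abs(sum(beta)) > 1e-10) next
      # bias interval from the remaining KKT inequalities
      r <- y - drop(K %*% beta)
      lb <- suppressWarnings(max(r[st == 3] + epsilon, r[st == 1] - epsilon))
      ub <- suppressWarnings(min(r[st == 2] - epsilon, r[st == 1] + epsilon))
      if (!is.finite(lb)) lb <- ub
      if (!is.finite(ub)) ub <- lb
      if (lb > ub + 1e-10) next
      b <- (lb + ub) / 2
    }
    # full KKT feasibility at this (beta, b)
    r <- y - drop(K %*% beta) - b
    ok <- TRUE
    tol <- 1e-8 * max(1, C)
    for (i in seq_len(n)) {
      ok <- ok && switch(st[i],
        abs(r[i]) <= epsilon + tol,        # interior
        r[i] >= epsilon - tol,             # at +C
        r[i] <= -epsilon + tol,            # at -C
        abs(r[i] - epsilon) <= tol,        # free positive
        abs(r[i] + epsilon) <= tol)        # free negative
      if (!ok) break
    }
    if (!ok) next
    val <- dual_value(beta)
    if (is.null(best) || val > best$objective) {
      best <- list(beta = beta, b = b, objective = val)
    }
  }
  stopifnot(!is.null(best))
  best$predict <- function(Xnew) {
    drop(rbf_kernel(Xnew, X, gamma) %*% best$beta) + best$b
  }
  best
}
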