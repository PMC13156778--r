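test_that("permutation importance isolates the active feature", {
  set.seed(40)
  X <- matrix(runif(300), ncol = 3)
  colnames(X) <- c("a", "b", "c")
  model <- fn_model(function(x) x[1])
  y <- X[, 1] + 1e-6 * rnorm(100)
  pi_tbl <- permutation_importance(model, X, y, n_rep = 20, seed = 1)
  expect_gt(pi_tbl$pi[1], 100 * max(abs(pi_tbl$pi[2:3])))
  expect_lt(abs(pi_tbl$pi[2]), 0.02)

  again <- permutation_importance(model, X, y, n_rep = 20, seed = 1)
  expect_equal(pi_tbl$pi, again$pi, tolerance = 1e-6)
  expect_error(permutation_importance(model, X, X[, 1], seed = 1), "zero")
})

test_that("partial dependence recovers additive components up to a constant", {
  set.seed(41)
  X <- matrix(runif(400), ncol = 2)
  colnames(X) <- c("a", "b")
  g <- function(x) sin(3 * x)
  h <- function(x) x^2
  model <- fn_model(function(x) g(x[1]) + h(x[2]))
  curves <- partial_dependence(model, X, grid_size = 30)
  ca <- curves[curves$feature == "a", ]
  expect_lt(max(abs((ca$pd - mean(ca$pd)) -
                      (g(ca$value) - mean(g(ca$value))))), 1e-10)
  rng <- pd_ranges(curves)
  expect_equal(sum(rng$pdr), 1)
})

test_that("flat or irrelevant features get zero or uniform PDR", {
  X <- matrix(runif(200), ncol = 2)
  colnames(X) <- c("a", "b")
  only_a <- fn_model(function(x) 2 * x[1])
  rng <- pd_ranges(partial_dependence(only_a, X))
  expect_equal(rng$pdr[rng$feature == "b"], 0)
  flat <- fn_model(function(x) 1)
  expect_warning(rngf <- pd_ranges(partial_dependence(flat, X)), "flat")
  expect_equal(rngf$pdr, c(0.5, 0.5))
})

test_that("support-vector contributions are normalized coordinate masses", {
  m <- fit_svr(matrix(runif(60), ncol = 3), y = rnorm(20), C = 10, gamma = 1,
               epsilon = 0.01, scale = FALSE)
  svc <- sv_contribution(m)
  expect_equal(sum(svc$sv), 1)

  # hand-built model with a single support vector at (0.5, 0.5)
  one <- structure(list(beta = 2, b = 0, support = 1L,
                        X = matrix(c(0.5, 0.5), nrow = 1),
                        features = c("a", "b")), class = "svr_fit")
  expect_equal(sv_contribution(one)$sv, c(0.5, 0.5))

  # feature at zero in every support vector contributes nothing
  zerocol <- structure(list(beta = c(1, -2), b = 0, support = 1:2,
                            X = cbind(c(0.2, 0.7), c(0, 0)),
                            features = c("a", "b")), class = "svr_fit")
  expect_equal(sv_contribution(zerocol)$sv[2], 0)
})

test_that("fusion weights, normalization and ranking behave as documented", {
  f <- fuse_importance(c(0, 1), c(1, 0), c(1, 0), features = c("a", "b"))
  expect_equal(f$fused, c(0.5, 0.5))
  expect_equal(f$rank, c(1L, 1L))

  pi_only <- fuse_importance(c(0.1, 0.9, 0.4), c(1, 2, 3), c(0.2, 0.3, 0.5),
                             weights = c(1, 0, 0))
  expect_equal(pi_only$fused, (c(0.1, 0.9, 0.4) - 0.1) / 0.8)

  # invariant to positive rescaling of any component
  a <- fuse_importance(c(1, 5, 3), c(2, 1, 4), c(0.1, 0.5, 0.4))
  b <- fuse_importance(c(10, 50, 30), c(2, 1, 4) * 7, c(0.1, 0.5, 0.4))
  expect_equal(a$fused, b$fused)

  expect_warning(u <- fuse_importance(c(1, 1), c(0, 1), c(0, 1)), "uniform")
  expect_error(fuse_importance(1:2, 1:3, 1:2), "equal length")
  expect_error(fuse_importance(1:2, 1:2, 1:2, weights = c(1, 1, 1)), "summing")
})

test_that("the full importance report is assembled with attached curves", {
  m <- fit_svr(data_noisy, C = 10, gamma = 1, epsilon = 0.01)
  imp <- feature_importance(m, n_rep = 3, seed = 5, grid_size = 15)
  expect_s3_class(imp, "importance_report")
  expect_equal(nrow(imp), 6)
  expect_setequal(imp$rank, 1:6)
  expect_true(all(imp$fused >= 0 & imp$fused <= 1))
  expect_equal(sum(imp$sv), 1)
  curves <- attr(imp, "pd_curves")
  expect_equal(dplyr::n_distinct(curves$feature), 6)
})
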