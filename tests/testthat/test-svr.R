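test_that("the RBF kernel has its defining properties", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  set.seed(4)
  u <- rnorm(5); v <- rnorm(5)
  expect_equal(rbf_kernel(u, v, 0.7), rbf_kernel(v, u, 0.7))
  expect_error(rbf_kernel(1:2, 1:3, 1), "dimension")
  expect_error(rbf_kernel(1:2, 1:2, 0), "positive")
})

test_that("constant responses give an all-zero dual and a constant predictor", {
  X <- matrix(runif(20), ncol = 2)
  m <- fit_svr(X, y = rep(5, 10), C = 10, gamma = 1, epsilon = 0.1,
               scale = FALSE)
  expect_equal(m$beta, rep(0, 10))
  expect_equal(length(m$support), 0)
  expect_equal(predict(m, X), rep(5, 10))
})

test_that("hard-margin fits interpolate distinct points", {
  X <- matrix(c(0.1, 0.5, 0.9), ncol = 1)
  y <- c(1, 3, 2)
  m <- fit_svr(X, y = y, C = 1e6, gamma = 1, epsilon = 0, scale = FALSE)
  expect_equal(predict(m, X), y, tolerance = 1e-5)
})

test_that("the SMO solution satisfies the KKT conditions", {
  set.seed(8)
  n <- 50
  X <- matrix(runif(n * 3), n)
  y <- 2 + sin(4 * X[, 1]) - X[, 2] + 0.05 * rnorm(n)
  for (C in c(1, 100)) {
    eps <- 0.05
    m <- fit_svr(X, y = y, C = C, gamma = 2, epsilon = eps, scale = FALSE)
    r <- y - predict(m, X)
    free <- abs(m$beta) > 1e-8 * C & abs(m$beta) < C * (1 - 1e-6)
    bound <- abs(m$beta) >= C * (1 - 1e-6)
    inside <- abs(m$beta) <= 1e-8 * C
    expect_true(all(abs(abs(r[free]) - eps) < 1e-4))
    expect_true(all(abs(r[bound]) >= eps - 1e-4))
    expect_true(all(abs(r[inside]) <= eps + 1e-4))
    expect_lt(abs(sum(m$beta)), 1e-6 * C * n)
    expect_lt(m$gap, 1e-6)
  }
})

test_that("predictions agree with an established SVR implementation", {
  set.seed(15)
  for (rep in 1:3) {
    n <- 30 + 10 * rep
    X <- matrix(runif(n * 4), n)
    y <- 10 + X[, 1]^2 - 2 * X[, 2] * X[, 3] + 0.1 * rnorm(n)
    C <- c(1, 10, 100)[rep]
    m <- fit_svr(X, y = y, C = C, gamma = 1, epsilon = 0.01, scale = FALSE)
    sv <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                     cost = C, gamma = 1, epsilon = 0.01, scale = FALSE)
    rms <- sqrt(mean((predict(m, X) - predict(sv, X))^2))
    expect_lt(rms, 1e-3)
  }
})

test_that("degenerate hyperparameters and inputs are rejected", {
  X <- matrix(runif(10), ncol = 1)
  expect_error(fit_svr(X, y = runif(10), C = -1), "C > 0")
  expect_error(fit_svr(X, y = NULL), "y")
  m <- fit_svr(X, y = runif(10), C = 1, gamma = 1, epsilon = 0.1,
               scale = FALSE)
  expect_warning(predict(m, matrix(5, ncol = 1)), "unscaled")
})

test_that("nested CV evaluates the full grid per fold and is seed-deterministic", {
  grid <- svr_default_grid()
  expect_equal(nrow(grid), 100)

  small_grid <- grid[grid$C %in% c(1, 10) & grid$gamma %in% c(0.1, 1) &
                       grid$epsilon %in% c(0.01, 0.1), ]
  cv <- svr_tune_nested(data_noisy, grid = small_grid, seed = 7)
  # every (combo, fold) cell evaluated
  expect_equal(nrow(cv$inner), nrow(small_grid) * 5)
  expect_true(all(table(cv$inner$fold) == nrow(small_grid)))
  # chosen values come from the grid
  expect_true(all(cv$outer$C %in% small_grid$C))
  expect_true(all(cv$final$gamma %in% small_grid$gamma))

  cv2 <- svr_tune_nested(data_noisy, grid = small_grid, seed = 7)
  expect_identical(cv$outer, cv2$outer)
  expect_identical(cv$final, cv2$final)

  expect_error(svr_tune_nested(data_noisy, grid = grid[0, ]), "empty")
  expect_error(svr_tune_nested(data_noisy[1:6, ], grid = small_grid), "fold")
})
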