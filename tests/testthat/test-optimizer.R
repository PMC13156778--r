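test_that("multistart ascent finds simple optima", {
  opt <- maximize_surrogate(function(x) -(x[1] - 0.3)^2,
                            bounds = rbind(c(0, 1)), seed = 1)
  expect_equal(opt$par, 0.3, tolerance = 1e-6)
  expect_equal(opt$value, 0, tolerance = 1e-10)

  lin <- maximize_surrogate(function(x) 2 * x[1] - x[2],
                            bounds = rbind(c(-1, 1), c(-1, 1)), seed = 2)
  expect_equal(lin$par, c(1, -1), tolerance = 1e-6)
})

test_that("a concave 6-d quadratic matches its closed-form stationary point", {
  set.seed(3)
  A <- matrix(rnorm(36), 6)
  B <- -(A %*% t(A)) - diag(6) * 0.5
  g <- rnorm(6)
  xstar <- -solve(B, g)
  stopifnot(all(abs(xstar) < 1))  # interior point
  f <- function(x) sum(g * x) + 0.5 * drop(t(x) %*% B %*% x)
  opt <- maximize_surrogate(f, cbind(rep(-1, 6), rep(1, 6)),
                            n_starts = 32, seed = 5)
  expect_equal(opt$par, xstar, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(opt$value, f(xstar), tolerance = 1e-9)
})

test_that("the returned optimum dominates every evaluated start", {
  f <- function(x) sin(5 * x[1]) * cos(3 * x[2])
  opt <- maximize_surrogate(f, cbind(c(0, 0), c(1, 1)), n_starts = 16, seed = 9)
  expect_true(all(opt$value >= opt$starts$value[!opt$starts$skipped] - 1e-12))
  # deterministic under seed
  opt2 <- maximize_surrogate(f, cbind(c(0, 0), c(1, 1)), n_starts = 16, seed = 9)
  expect_identical(opt$par, opt2$par)
})

test_that("non-finite starts are skipped and bad bounds rejected", {
  f <- function(x) if (x[1] < 0.5) NaN else -(x[1] - 0.7)^2
  opt <- maximize_surrogate(f, rbind(c(0, 1)), n_starts = 16, seed = 4)
  expect_equal(opt$par, 0.7, tolerance = 1e-5)
  expect_true(any(opt$starts$skipped))
  expect_error(maximize_surrogate(f, rbind(c(1, 0))), "low < high")
})

test_that("practical rounding reproduces the reported operating settings", {
  got <- round_to_practice(c(137.86, 0.55, 35.05, 25.9, 325.4, 56.35),
                           c(1, 0.05, 1, 1, 5, 0.5))
  expect_equal(got, c(138, 0.55, 35, 26, 325, 56.5))
  # on-grid values unchanged; half-step ties round away from zero
  expect_equal(round_to_practice(c(35, 0.55), c(1, 0.05)), c(35, 0.55))
  expect_equal(round_to_practice(2.5, 1), 3)
  expect_equal(round_to_practice(56.25, 0.5), 56.5)
  expect_error(round_to_practice(1, c(1, 2)), "lengths")
  expect_error(round_to_practice(1, -1), "positive")
})

test_that("maximizing the fitted surface beats the center point", {
  fit <- suppressWarnings(fit_rsm(data_exact))
  opt <- optimize_yield(fit, paper_factors, n_starts = 24, seed = 11)
  expect_gt(opt$predicted, 19.33)
  expect_true(all(abs(opt$coded) <= 1 + 1e-9))
  # practical settings sit on their resolution grids
  res <- crp_resolutions()[paper_factors$name]
  expect_equal(opt$practical, res * round(opt$practical / res),
               tolerance = 1e-9)
})
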