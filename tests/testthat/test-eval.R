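test_that("regression metrics match hand arithmetic and limiting cases", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-4)
  expect_equal(m$mae, 1 / 3, tolerance = 1e-4)
  expect_equal(m$r.squared, 0.5)
  expect_equal(m$mape, 100 / 9, tolerance = 1e-4)

  perfect <- regression_metrics(c(2, 4, 8), c(2, 4, 8))
  expect_equal(unlist(perfect[c("r.squared", "rmse", "mae", "mape")]),
               c(r.squared = 1, rmse = 0, mae = 0, mape = 0))

  y <- rnorm(20)
  expect_equal(regression_metrics(y, rep(mean(y), 20))$r.squared, 0)
  expect_warning(mz <- regression_metrics(c(0, 1), c(1, 1)), "MAPE")
  expect_true(is.na(mz$mape))
})

test_that("RMSE dominates MAE on random data", {
  set.seed(20)
  for (i in 1:10) {
    y <- rnorm(15)
    m <- regression_metrics(y, y + rnorm(15))
    expect_gte(m$rmse, m$mae)
  }
})

test_that("the generalization-gap rule applies the 0.10 threshold", {
  g <- generalization_gap(0.9907, 0.9027)
  expect_equal(g$delta_r2, 0.0880, tolerance = 1e-10)
  expect_true(g$acceptable)
  expect_equal(generalization_gap(0.7, 0.7)$delta_r2, 0)
  expect_false(generalization_gap(0.99, 0.85)$acceptable)
})

test_that("the paired error test matches hand arithmetic", {
  # |e1| - |e2| = (1, 2, 3)
  r <- paired_error_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p.value, 0.0742, tolerance = 1e-3)
  # swapping the two models flips the sign but not the p-value
  r2 <- paired_error_test(c(1, 1, 1), c(2, 3, 4))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p.value, r$p.value)
  expect_warning(deg <- paired_error_test(c(1, 2), c(1, 2)), "degenerate")
  expect_equal(deg$p.value, 1)
})

test_that("the Durbin-Watson statistic matches its definition", {
  expect_equal(durbin_watson(c(1, -1, 1, -1, 1)), 16 / 5)
  set.seed(30)
  e <- as.numeric(arima.sim(list(ar = 0.5), n = 4000))
  expect_equal(durbin_watson(e), 2 * (1 - 0.5), tolerance = 0.1)
})

test_that("the diagnostics battery reports five tests with valid p-values", {
  set.seed(31)
  res <- rnorm(100)
  fit <- rnorm(100)
  d <- residual_diagnostics(res, fit)
  expect_equal(d$test, c("lilliefors", "jarque_bera", "anderson_darling",
                         "breusch_pagan", "durbin_watson"))
  ps <- d$p.value[!is.na(d$p.value)]
  expect_true(all(ps >= 0 & ps <= 1))
  # well-behaved residuals should not be flagged at tiny levels
  expect_true(all(ps > 1e-4))
})

test_that("Breusch-Pagan detects variance proportional to the fitted values", {
  set.seed(32)
  hits <- 0
  for (i in 1:20) {
    fit <- runif(200, 1, 5)
    res <- rnorm(200, sd = sqrt(fit))
    p <- residual_diagnostics(res, fit)$p.value[4]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 18)  # power > 0.9
})

test_that("degenerate residuals are reported as such", {
  expect_warning(d <- residual_diagnostics(rep(1, 20), rnorm(20)), "Constant")
  expect_true(all(is.na(d$statistic)))
})

test_that("model comparison assembles metrics, paired test and gaps", {
  set.seed(33)
  y <- rnorm(17, 18, 2)
  pa <- y + rnorm(17, sd = 0.3)
  pb <- y + rnorm(17, sd = 0.8)
  cmp <- compare_models(y, pa, pb, train_r2_a = 0.99, train_r2_b = 0.95)
  expect_equal(cmp$metrics$model, c("svr", "rsm"))
  expect_equal(nrow(cmp$gaps), 2)
  expect_s3_class(cmp$paired_test, "tbl_df")
})
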