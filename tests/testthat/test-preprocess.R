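test_that("min-max scaling maps, inverts and rejects constant columns", {
  X <- cbind(a = c(2, 4, 6), b = c(-1, 0, 3))
  p <- minmax_fit(X)
  S <- minmax_apply(X, p)
  expect_equal(S[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(minmax_invert(S, p), X, tolerance = 1e-12)
  expect_error(minmax_fit(cbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("Mahalanobis screen uses the documented chi-squared threshold", {
  set.seed(11)
  X <- matrix(rnorm(600), ncol = 6)
  scr <- mahalanobis_screen(X)
  expect_equal(attr(scr, "threshold"), 22.46, tolerance = 0.005)
  # a row equal to the mean has distance zero
  X2 <- rbind(X, colMeans(X))
  d2 <- mahalanobis_screen(X2)$d2
  expect_lt(d2[length(d2)], 1e-10)
})

test_that("screen flag rate matches the nominal tail mass", {
  set.seed(42)
  X <- matrix(rnorm(10000 * 6), ncol = 6)
  scr <- mahalanobis_screen(X)
  expect_equal(mean(scr$outlier), 0.001, tolerance = 0.001)
})

test_that("singular covariance is rejected with guidance", {
  X <- cbind(1:10, 2 * (1:10), rnorm(10))
  expect_error(mahalanobis_screen(X), "singular")
})

test_that("stratified split reproduces the 69/17 partition and stays stratified", {
  set.seed(5)
  y <- rnorm(86)
  sp <- stratified_split(y, test_frac = 0.2, n_strata = 5, seed = 9)
  expect_equal(sum(sp$label == "train"), 69)
  expect_equal(sum(sp$label == "test"), 17)
  expect_equal(sort(sp$index), 1:86)
  # per-stratum test share off by at most one item from the target
  tab <- table(sp$stratum, sp$label)
  per <- tab[, "test"]
  sizes <- rowSums(tab)
  expect_true(all(abs(per - sizes * 0.2) <= 1))

  sp2 <- stratified_split(y, test_frac = 0.2, n_strata = 5, seed = 9)
  expect_identical(sp, sp2)

  small <- stratified_split(rnorm(10), test_frac = 0.2, n_strata = 2, seed = 1)
  expect_equal(sum(small$label == "test"), 2)
  expect_equal(unname(table(small$stratum, small$label)[, "test"]), c(1L, 1L))
  expect_error(stratified_split(y, test_frac = 1.2), "test_frac")
})

test_that("variance inflation factors match closed forms", {
  set.seed(2)
  # balanced factorial contrasts: centered, mutually orthogonal -> VIF 1
  Q <- cbind(rep(c(-1, 1), 50),
             rep(c(-1, -1, 1, 1), 25),
             rep(c(-1, 1, 1, -1), 25))
  expect_equal(vif_scores(Q)$vif, rep(1, 3), tolerance = 1e-10)

  # exact sample correlation 0.8 -> VIF = 1/(1-0.64)
  x <- scale(rnorm(100))[, 1]
  z <- scale(resid(lm(rnorm(100) ~ x)))[, 1]
  y <- 0.8 * x + sqrt(1 - 0.64) * z
  expect_equal(vif_scores(cbind(x, y))$vif, rep(1 / (1 - 0.64), 2),
               tolerance = 1e-6)

  # duplicated column -> infinite
  expect_true(all(is.infinite(vif_scores(cbind(x, x))$vif)))
})
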