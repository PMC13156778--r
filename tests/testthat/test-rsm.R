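test_that("noise-free data returns the generating coefficients exactly", {
  fit <- suppressWarnings(fit_rsm(data_exact))
  expect_equal(length(fit$labels), 27)  # 6 + 15 + 6 non-intercept terms
  expect_lt(max(abs(tidy(fit)$estimate - surface_coefs())), 1e-8)
  # prediction at a design point equals the fitted value
  expect_equal(predict(fit, data_exact[3, ]), predict(fit)[3], tolerance = 1e-9)
})

test_that("under-determined or aliased designs are rejected", {
  expect_error(fit_rsm(data_noisy[1:20, ]), "more than")
  dup <- data_noisy
  dup$coded_temp <- dup$coded_power  # aliases power with temperature
  expect_error(fit_rsm(dup), "aliased")
})

test_that("the ANOVA decomposition satisfies its identities", {
  fit <- fit_rsm(data_noisy)
  an <- rsm_anova(fit)
  get <- function(t, col) an[[col]][an$term == t]
  expect_equal(get("Model", "ss") + get("Residual", "ss"),
               get("Total (corr.)", "ss"), tolerance = 1e-9)
  expect_equal(get("Lack of fit", "ss") + get("Pure error", "ss"),
               get("Residual", "ss"), tolerance = 1e-9)
  expect_equal(get("Model", "df") + get("Residual", "df"),
               get("Total (corr.)", "df"))
  expect_equal(get("Lack of fit", "df"), 49L)
  expect_equal(get("Pure error", "df"), 9L)
  ps <- an$p.value[!is.na(an$p.value)]
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(an$statistic[!is.na(an$statistic)] >= 0))
  # sequential SS are additive to the model SS (partial SS need not be,
  # since quadratic terms are not orthogonal to the intercept)
  seq_an <- rsm_anova(fit, type = "sequential")
  terms <- setdiff(seq_an$term, c("Model", "Residual", "Lack of fit",
                                  "Pure error", "Total (corr.)"))
  expect_equal(sum(seq_an$ss[seq_an$term %in% terms]),
               seq_an$ss[seq_an$term == "Model"], tolerance = 1e-9)
})

test_that("partial SS reduce to coef^2 times column SS on the orthogonal design", {
  fit <- fit_rsm(data_noisy)
  an <- rsm_anova(fit)
  coded <- design_matrix(data_noisy, "coded")
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  # a linear term
  ss_lin <- an$ss[an$term == "sonic_time"]
  expect_equal(ss_lin, est[["sonic_time"]]^2 * sum(coded[, "sonic_time"]^2),
               tolerance = 1e-8)
  # an interaction term
  inter <- coded[, "soak_time"] * coded[, "naoh"]
  ss_int <- an$ss[an$term == "soak_time:naoh"]
  expect_equal(ss_int, est[["soak_time:naoh"]]^2 * sum(inter^2),
               tolerance = 1e-8)
})

test_that("lack-of-fit and R2 helpers reproduce the printed ANOVA arithmetic", {
  lt <- lack_of_fit_test(30.70, 49, 3.62, 9)
  expect_equal(lt$statistic, 1.56, tolerance = 0.005)
  expect_equal(lt$p.value, 0.2443, tolerance = 0.01)
  expect_equal(r_squared_from_ss(34.32, 302.05), 0.8864, tolerance = 5e-5)
})

test_that("PRESS matches brute-force leave-one-out refits", {
  fit <- fit_rsm(data_noisy)
  X <- cbind(1, quad_basis <- model.matrix(fit$lm)[, -1])
  y <- fit$y
  press_brute <- sum(vapply(seq_along(y), function(i) {
    b <- qr.coef(qr(X[-i, , drop = FALSE]), y[-i])
    (y[i] - sum(X[i, ] * b))^2
  }, numeric(1)))
  h <- lm.influence(fit$lm, do.coef = FALSE)$hat
  press_hat <- sum((resid(fit$lm) / (1 - h))^2)
  expect_equal(press_hat, press_brute, tolerance = 1e-9)
  expect_equal(predicted_r2(fit), 1 - press_brute / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_lte(predicted_r2(fit), glance(fit)$r.squared)
})

test_that("designs without replicates drop the lack-of-fit rows with a warning", {
  norep <- data_noisy[data_noisy$run_type != "center", ]
  extra <- data_noisy[data_noisy$run_type == "center", ][1, ]
  norep <- dplyr::bind_rows(norep, extra)  # 77 runs, no replicated point
  fit <- fit_rsm(norep)
  expect_warning(an <- rsm_anova(fit), "replicated")
  expect_false(any(an$term %in% c("Lack of fit", "Pure error")))
})
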