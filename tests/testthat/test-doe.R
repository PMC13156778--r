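test_that("axial distance rules give the documented values and reject bad k", {
  expect_equal(practical_alpha(6), 6^0.25, tolerance = 1e-12)
  expect_equal(round(practical_alpha(6), 4), 1.5651)
  expect_equal(rotatable_alpha(4), sqrt(2), tolerance = 1e-12)
  expect_error(practical_alpha(1), "k")
  expect_error(practical_alpha(2.5), "k")
})

test_that("coded/actual conversion reproduces printed factor levels and inverts", {
  power <- paper_factors[paper_factors$name == "power", ]
  expect_equal(unname(drop(coded_to_actual(power, paper_alpha, round = TRUE))), 556.5)
  expect_equal(unname(drop(coded_to_actual(power, 0))), 400)
  soak <- paper_factors[paper_factors$name == "soak_time", ]
  expect_equal(unname(drop(coded_to_actual(soak, -1))), 60)

  coded <- matrix(runif(60, -2, 2), ncol = 6)
  actual <- coded_to_actual(paper_factors, coded)
  expect_equal(actual_to_coded(paper_factors, actual), coded,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("every printed five-level table cell is reconstructed", {
  printed <- rbind(
    soak_time  = c(26.1, 60, 120, 180, 213.9),
    naoh       = c(0.34, 0.4, 0.5, 0.6, 0.66),
    sonic_time = c(14.3, 20, 30, 40, 45.7),
    ls_ratio   = c(17.2, 20, 25, 30, 32.8),
    power      = c(243.5, 300, 400, 500, 556.5),
    temp       = c(44.3, 50, 60, 70, 75.7)
  )
  levels <- c(-paper_alpha, -1, 0, 1, paper_alpha)
  got <- sapply(levels, function(cc) {
    drop(coded_to_actual(paper_factors, rep(cc, 6), round = TRUE))
  })
  expect_equal(unname(got), unname(printed))
})

test_that("full CCD has the documented block structure", {
  expect_equal(nrow(paper_design), 86)
  counts <- table(paper_design$run_type)
  expect_equal(unname(counts[c("factorial", "axial", "center")]),
               c(64L, 12L, 10L), ignore_attr = TRUE)

  coded <- design_matrix(paper_design, "coded")
  expect_true(all(abs(colSums(coded)) < 1e-10))
  for (j in 1:6) {
    expect_setequal(round(unique(coded[, j]), 6),
                    round(c(-paper_alpha, -1, 0, 1, paper_alpha), 6))
  }
  fact <- coded[paper_design$run_type == "factorial", ]
  expect_true(all(fact %in% c(-1, 1)))
  axial <- coded[paper_design$run_type == "axial", ]
  expect_true(all(rowSums(axial != 0) == 1))
  expect_true(all(abs(axial[axial != 0]) - paper_alpha < 1e-12))
  expect_true(all(coded[paper_design$run_type == "center", ] == 0))
})

test_that("linear coded columns are mutually orthogonal and orthogonal to interactions", {
  coded <- design_matrix(paper_design, "coded")
  G <- crossprod(coded)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-9))
  pairs <- combn(6, 2)
  for (p in seq_len(ncol(pairs))) {
    inter <- coded[, pairs[1, p]] * coded[, pairs[2, p]]
    expect_true(all(abs(crossprod(coded, inter)) < 1e-9))
  }
})

test_that("small designs, seeds and error cases behave", {
  d2 <- ccd_design(dplyr::bind_rows(
    factor_spec("a", "u", 0, 1), factor_spec("b", "u", 0, 1)
  ), alpha = sqrt(2), n_center = 5, seed = 3)
  expect_equal(nrow(d2), 13)

  # content is seed independent, order is not
  dA <- ccd_design(paper_factors, n_center = 10, seed = 1)
  dB <- ccd_design(paper_factors, n_center = 10, seed = 2)
  mA <- design_matrix(dA, "coded")
  mB <- design_matrix(dB, "coded")
  ordstr <- function(m) sort(apply(round(m, 8), 1, paste, collapse = "|"))
  expect_identical(ordstr(mA), ordstr(mB))
  expect_false(identical(mA, mB))
  expect_identical(as.data.frame(dA),
                   as.data.frame(ccd_design(paper_factors, n_center = 10, seed = 1)))

  expect_error(ccd_design(paper_factors[1, , drop = FALSE]), "2 to 8")
  bad <- paper_factors
  expect_error(factor_spec("x", "u", 1, step = -1), "positive")
  expect_error(ccd_design(paper_factors, n_center = 0), "n_center")
})
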