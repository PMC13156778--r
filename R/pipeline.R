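#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()] with the study defaults:
#' the six-factor table, the published fitted surface as synthetic truth,
#' pure-error-calibrated noise, an 80/20 quintile-stratified split, the
#' 100-point SVR grid, 0.50/0.25/0.25 importance fusion and the
#' conventional-extraction economic reference.
#'
#' @param factors Factor table.
#' @param surface A [surface_spec()] used to simulate responses.
#' @param n_center Center replicates in the design.
#' @param seeds Named list of integer seeds: `design`, `noise`, `split`,
#'   `cv`, `importance`, `optimizer`.
#' @param test_frac,n_strata Split parameters.
#' @param grid SVR hyperparameter grid.
#' @param k_folds Folds for nested CV.
#' @param importance_weights Fusion weights (PI, PDR, SV).
#' @param n_rep Permutation-importance repeats.
#' @param n_starts Optimizer multistarts.
#' @param econ List of economic scenario parameters (see defaults).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(factors = crp_factors(),
                            surface = crp_yield_surface(),
                            n_center = 10L,
                            seeds = list(design = 101L, noise = 202L,
                                         split = 303L, cv = 404L,
                                         importance = 505L, optimizer = 606L),
                            test_frac = 0.2, n_strata = 5L,
                            grid = svr_default_grid(), k_folds = 5L,
                            importance_weights = c(0.50, 0.25, 0.25),
                            n_rep = 30L, n_starts = 64L,
                            econ = list(
                              reference = list(method = "CAE", yield_pct = 13.07,
                                               total_time_min = 260,
                                               extraction_time_h = 2,
                                               power_kw = 1.2),
                              center = list(method = "CCD center",
                                            yield_pct = 19.24,
                                            total_time_min = 150,
                                            extraction_time_h = 0.5,
                                            power_kw = 0.4),
                              batch_raw_kg = 0.020, ef = 0.4671,
                              validated_yield_pct = 20.09,
                              validated_total_time_min = 173,
                              validated_extraction_time_h = 35 / 60
                            )) {
  cfg <- list(
    factors = factors, surface = surface, n_center = n_center, seeds = seeds,
    test_frac = test_frac, n_strata = n_strata, grid = grid,
    k_folds = k_folds, importance_weights = importance_weights,
    n_rep = n_rep, n_starts = n_starts, econ = econ
  )
  class(cfg) <- "pipeline_config"
  cfg
}

check_seeds <- function(seeds) {
  required <- c("design", "noise", "split", "cv", "importance", "optimizer")
  missing <- setdiff(required, names(seeds))
  if (length(missing) > 0L) {
    abort(paste0("Missing pipeline seed(s): ",
                 paste0("seeds.", missing, collapse = ", ")))
  }
  bad <- names(seeds)[!vapply(seeds, function(s) {
    is.numeric(s) && length(s) == 1L && is.finite(s) && s == round(s)
  }, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("Non-integer pipeline seed(s): ",
                 paste0("seeds.", bad, collapse = ", ")))
  }
  lapply(seeds, as.integer)
}

#' Run the full design-to-economics workflow
#'
#' Executes every stage in order: build the design, simulate (or accept)
#' responses, Mahalanobis screen, variance inflation factors, stratified
#' split, response-surface fit with full ANOVA, nested-CV SVR, test-set
#' comparison with paired error test and residual diagnostics, tri-metric
#' importance fusion, surrogate maximization with practical rounding, and
#' techno-economic reports. All stages are pure functions of the
#' configuration and its seeds, so a rerun reproduces identical numbers.
#'
#' @param config A [pipeline_config()].
#' @param data Optional run table with `coded_*`/`actual_*` columns and
#'   `yield_pct`, replacing the simulation stage.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written (`design.csv`, `dataset.csv`, `anova.csv`, `rsm.json`,
#'   `cv.csv`, `svr.json`, `comparison.csv`, `importance.json`,
#'   `optimum.json`, `econ.csv`, `log.txt`).
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result` with the stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  seeds <- check_seeds(config$seeds)
  say <- function(...) if (!quiet) message(sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  say("stage design")
  design <- stage("design", ccd_design(config$factors, n_center = config$n_center,
                                       seed = seeds$design))

  say("stage simulate")
  dataset <- stage("simulate", {
    if (is.null(data)) {
      simulate_yield(design, config$surface, seed = seeds$noise)
    } else {
      if (!"yield_pct" %in% names(data)) abort("`data` lacks a yield_pct column.")
      data
    }
  })

  say("stage screen")
  actual <- design_matrix(dataset, "actual")
  screen <- stage("screen", mahalanobis_screen(actual))
  vifs <- stage("vif", vif_scores(actual))

  say("stage split")
  split <- stage("split", stratified_split(dataset$yield_pct,
                                           test_frac = config$test_frac,
                                           n_strata = config$n_strata,
                                           seed = seeds$split))
  train <- dataset[split$label == "train", ]
  test <- dataset[split$label == "test", ]

  say("stage fit-rsm")
  rsm_full <- stage("fit-rsm", fit_rsm(dataset))
  rsm_train <- stage("fit-rsm", fit_rsm(train))
  anova_tbl <- stage("fit-rsm", rsm_anova(rsm_full))

  say("stage fit-svr (nested CV)")
  cv <- stage("fit-svr", svr_tune_nested(train, grid = config$grid,
                                         k_folds = config$k_folds,
                                         seed = seeds$cv))
  svr <- cv$model

  say("stage compare")
  comparison <- stage("compare", {
    pred_svr <- predict(svr, test)
    pred_rsm <- predict(rsm_train, test)
    tr_svr <- regression_metrics(svr$y, predict(svr))$r.squared
    tr_rsm <- regression_metrics(train$yield_pct, predict(rsm_train))$r.squared
    cmp <- compare_models(test$yield_pct, pred_svr, pred_rsm,
                          train_r2_a = tr_svr, train_r2_b = tr_rsm)
    cmp$diagnostics <- residual_diagnostics(
      svr$y - predict(svr), predict(svr))
    cmp
  })

  say("stage importance")
  importance <- stage("importance", feature_importance(
    svr, n_rep = config$n_rep, seed = seeds$importance,
    weights = config$importance_weights))

  say("stage optimize")
  optimum <- stage("optimize", list(
    svr = optimize_yield(svr, config$factors, n_starts = config$n_starts,
                         seed = seeds$optimizer),
    rsm = optimize_yield(rsm_full, config$factors, n_starts = config$n_starts,
                         seed = seeds$optimizer)
  ))

  say("stage econ")
  econ <- stage("econ", {
    e <- config$econ
    ref <- e$reference
    dplyr::bind_rows(
      econ_report(ref$method, ref$yield_pct, ref$total_time_min,
                  ref$extraction_time_h, ref$power_kw,
                  batch_raw_kg = e$batch_raw_kg, ef = e$ef),
      econ_report(e$center$method, e$center$yield_pct,
                  e$center$total_time_min, e$center$extraction_time_h,
                  e$center$power_kw, batch_raw_kg = e$batch_raw_kg, ef = e$ef,
                  yield_ref = ref$yield_pct),
      econ_report("SVR optimum (validated)", e$validated_yield_pct,
                  e$validated_total_time_min, e$validated_extraction_time_h,
                  power_kw = optimum$svr$practical[["power"]] / 1000,
                  batch_raw_kg = e$batch_raw_kg, ef = e$ef,
                  yield_ref = ref$yield_pct)
    )
  })

  result <- structure(
    list(design = design, dataset = dataset, screen = screen, vif = vifs,
         split = split, rsm = rsm_full, rsm_train = rsm_train,
         anova = anova_tbl, cv = cv, svr = svr, comparison = comparison,
         importance = importance, optimum = optimum, econ = econ,
         seeds = seeds),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wcsv <- function(x, f) utils::write.csv(x, p(f), row.names = FALSE)
  wjson <- function(x, f) jsonlite::write_json(x, p(f), auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)

  wcsv(as.data.frame(result$design), "design.csv")
  wcsv(as.data.frame(result$dataset), "dataset.csv")
  wcsv(as.data.frame(result$anova), "anova.csv")
  wjson(setNames(as.list(result$rsm$terms$estimate), result$rsm$terms$term),
        "rsm.json")
  wcsv(as.data.frame(result$cv$outer), "cv.csv")
  wjson(list(C = result$svr$C, gamma = result$svr$gamma,
             epsilon = result$svr$epsilon, b = result$svr$b,
             support = result$svr$support,
             dual_coef = result$svr$beta[result$svr$support]),
        "svr.json")
  wcsv(as.data.frame(result$comparison$metrics), "comparison.csv")
  wjson(as.list(tibble::as_tibble(result$importance)), "importance.json")
  wjson(list(
    svr = list(actual = as.list(result$optimum$svr$actual),
               practical = as.list(result$optimum$svr$practical),
               predicted = result$optimum$svr$predicted),
    rsm = list(actual = as.list(result$optimum$rsm$actual),
               practical = as.list(result$optimum$rsm$practical),
               predicted = result$optimum$rsm$predicted)
  ), "optimum.json")
  wcsv(as.data.frame(result$econ), "econ.csv")
  writeLines(c(
    sprintf("sonoptim %s", as.character(utils::packageVersion("sonoptim"))),
    sprintf("R %s", R.version.string),
    sprintf("seeds: %s", paste(names(result$seeds), unlist(result$seeds),
                               sep = "=", collapse = ", "))
  ), p("log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Extraction-optimization pipeline result\n")
  cat(sprintf("  runs: %d (%d train / %d test), outliers flagged: %d\n",
              nrow(x$dataset), sum(x$split$label == "train"),
              sum(x$split$label == "test"), sum(x$screen$outlier)))
  cat(sprintf("  RSM R2 %.4f | SVR outer-CV mean R2 %.4f\n",
              attr(x$anova, "r.squared"), mean(x$cv$outer$r.squared)))
  top <- x$importance$feature[order(x$importance$rank)][1:2]
  cat(sprintf("  top importance: %s\n", paste(top, collapse = ", ")))
  cat(sprintf("  SVR optimum predicted yield %.2f%%\n",
              x$optimum$svr$predicted))
  invisible(x)
}
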