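test_that("stratified folds partition subjects and balance rate and time", {
  g <- generate_cohort(generator_config(n = 18288, seed = 19))
  time <- g$cohort$time_months
  event <- g$cohort$event
  fold <- stratified_splits(time, event, k = 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), length(time))
  overall_rate <- mean(event)
  overall_med <- c(stats::median(time[event == 1]),
                   stats::median(time[event == 0]))
  for (f in 1:5) {
    idx <- fold == f
    expect_lt(abs(mean(event[idx]) - overall_rate), 0.01)
    expect_lt(abs(stats::median(time[idx & event == 1]) - overall_med[1]),
              0.1 * overall_med[1])
    expect_lt(abs(stats::median(time[idx & event == 0]) - overall_med[2]),
              0.1 * overall_med[2])
  }
  expect_identical(fold, stratified_splits(time, event, k = 5, seed = 3))
})

test_that("a single-point hyperparameter grid short-circuits", {
  d <- make_ph_cohort(200, seed = 81)
  reg <- default_model_registry()
  out <- tune_hyperparams(reg$CoxPH, d$x, d$time, d$event)
  expect_equal(out$hyper, list())
  expect_true(is.na(out$score))
})

test_that("tuning rejects a degenerate shrinkage setting", {
  d <- make_normal_cohort(500, seed = 82)
  ctor <- list(
    fit = function(x, time, event, hyper)
      fit_mtlr(x, time, event, C = hyper$C),
    predict = function(object, x, grid = NULL) mtlr_predict(object, x),
    hyper_grid = list(list(C = 0.1), list(C = 1000)),
    tune_metric = "l1_hinge")
  out <- tune_hyperparams(ctor, d$x, d$time, d$event, inner_k = 3,
                          seed = 5)
  expect_equal(out$hyper$C, 0.1)
  out2 <- tune_hyperparams(ctor, d$x, d$time, d$event, inner_k = 3,
                           seed = 5)
  expect_identical(out, out2)
})

test_that("the default roster enumerates 135 configurations", {
  g <- enumerate_grid(grid_spec())
  expect_equal(nrow(g), 135)
  expect_equal(length(unique(g$config_id)), 135)
})

test_that("grid bookkeeping: rows equal configs times folds, skips explicit", {
  g <- make_clean_cohort(500, seed = 83, target_event_rate = 0.3)
  sp <- grid_spec(imputers = "median", selectors = "none",
                  models = c("CoxPH", "DeepHit"), outer_k = 3, seed = 2)
  res <- run_grid(sp, g$cohort, tune = FALSE)
  expect_equal(nrow(res$folds), 2 * 3)
  skips <- res$folds[res$folds$model == "DeepHit", ]
  expect_true(all(grepl("skipped", skips$status)))
  expect_true(all(is.na(skips$l1_hinge)))
  oks <- res$folds[res$folds$model == "CoxPH", ]
  expect_true(all(oks$status == "ok"))

  sp1 <- grid_spec(imputers = "median", selectors = "none",
                   models = "CoxPH", outer_k = 5, seed = 2)
  res1 <- run_grid(sp1, g$cohort, tune = FALSE)
  expect_equal(nrow(res1$folds), 5)
  expect_equal(nrow(res1$aggregate), 1)
})

test_that("the grid is reproducible under a fixed master seed", {
  g <- make_clean_cohort(400, seed = 84, target_event_rate = 0.3)
  sp <- grid_spec(imputers = "median", selectors = "univariate_cox",
                  models = "MTLR", outer_k = 3, seed = 11)
  r1 <- run_grid(sp, g$cohort, tune = FALSE)
  r2 <- run_grid(sp, g$cohort, tune = FALSE)
  expect_identical(r1$folds, r2$folds)
})

test_that("model selection follows the calibrated-lowest-loss-then-cindex rule", {
  mk <- function(id, loss, cindex, dcal) {
    data.frame(config_id = id, imputer = "m", selector = "s", model = id,
               n_folds = 5, n_scored = 5, l1_hinge_mean = loss,
               l1_hinge_sd = 0.1, c_index_mean = cindex, c_index_sd = 0.01,
               all_d_calibrated = dcal, status = "ok",
               stringsAsFactors = FALSE)
  }
  # a non-calibrated config with the lowest loss is rejected
  agg <- rbind(mk("deephit_like", 3.8, 0.58, FALSE),
               mk("mtlr_like", 7.2, 0.60, TRUE),
               mk("cox_like", 77.7, 0.61, TRUE))
  res <- structure(list(aggregate = agg), class = "grid_result")
  expect_equal(select_best_model(res), "mtlr_like")

  # ties on loss break by higher c-index
  agg2 <- rbind(mk("a", 10, 0.55, TRUE), mk("b", 10, 0.65, TRUE))
  expect_equal(select_best_model(structure(list(aggregate = agg2),
                                           class = "grid_result")), "b")

  # a single calibrated config wins regardless of loss
  agg3 <- rbind(mk("only", 500, 0.5, TRUE), mk("bad", 1, 0.9, FALSE))
  expect_equal(select_best_model(structure(list(aggregate = agg3),
                                           class = "grid_result")), "only")

  # nothing calibrated: NA with a diagnostic listing
  agg4 <- rbind(mk("x", 1, 0.6, FALSE), mk("y", 2, 0.6, FALSE))
  out <- select_best_model(structure(list(aggregate = agg4),
                                     class = "grid_result"))
  expect_true(is.na(out))
  expect_s3_class(attr(out, "diagnostic"), "data.frame")
  expect_equal(nrow(attr(out, "diagnostic")), 2)
})

test_that("an end-to-end mice + coxnet + mtlr pipeline is D-calibrated", {
  passes <- 0
  for (s in 1:3) {
    g <- generate_cohort(generator_config(n = 3000, seed = 900 + s,
                                          target_event_rate = 0.0331))
    sp <- grid_spec(imputers = "mice", selectors = "coxnet",
                    models = "MTLR", outer_k = 5, seed = s)
    res <- suppressWarnings(run_grid(sp, g$cohort, tune = FALSE))
    # every fold gets a row: scored, or an explicit error record (an
    # empty elastic-net selection in a sparse fold is legitimate)
    expect_equal(nrow(res$folds), 5)
    if (isTRUE(res$aggregate$all_d_calibrated) &&
        res$aggregate$n_scored == 5) passes <- passes + 1
  }
  expect_gte(passes, 2)
})

test_that("pipeline predictions respond to raw-feature edits end to end", {
  g <- make_clean_cohort(2500, seed = 85, target_event_rate = 0.25)
  pl <- fit_pipeline(g$cohort, imputer = "median", selector = "coxnet",
                     model = "MTLR", seed = 2)
  row <- g$cohort[7, ]
  schema <- attr(g$cohort, "schema")
  rep <- counterfactual_delta(pl, schema, row, "CDHQ1_SELENIUM_SPL",
                              schema$max[schema$name ==
                                           "CDHQ1_SELENIUM_SPL"])
  expect_s3_class(rep, "intervention_report")
  expect_equal(rep$delta,
               rep$counterfactual_median - rep$baseline_median)
})
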