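test_that("univariate cox screening keeps signal and discards noise", {
  set.seed(71)
  n <- 2000
  x <- cbind(signal = rnorm(n),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("noise", 1:20))))
  t0 <- rexp(n, exp(x[, "signal"]) / 60)
  cc <- runif(n, 10, 200)
  time <- pmin(t0, cc)
  event <- as.integer(t0 <= cc)    # ~30% events by construction
  sel <- univariate_cox_select(x, time, event, alpha = 0.001)
  expect_true("signal" %in% sel$kept)
  expect_lte(sum(grepl("noise", sel$kept)), 2)

  # a vacuous threshold keeps every convergent column
  sel_all <- univariate_cox_select(x, time, event, alpha = 1.0)
  expect_equal(length(sel_all$kept), 21)

  # constant columns are dropped with a log entry
  x2 <- cbind(x[, 1:2], flat = rep(1, n))
  sel2 <- univariate_cox_select(x2, time, event, alpha = 1.0)
  expect_false("flat" %in% sel2$kept)
  expect_true(any(grepl("flat", sel2$log)))
})

test_that("rfe keeps everything when n_keep = p and records elimination ranks", {
  d <- make_ph_cohort(300, seed = 72)
  x <- cbind(d$x, b = rnorm(300), c = rnorm(300))
  sel <- rfe_cox_select(x, d$time, d$event, n_keep = 3)
  expect_setequal(sel$kept, colnames(x))
  expect_true(all(is.na(sel$stat)))

  sel2 <- rfe_cox_select(x, d$time, d$event, n_keep = 1)
  ranks <- sel2$stat[!is.na(sel2$stat)]
  expect_setequal(unname(ranks), 1:2)
})

test_that("rfe retains the informative feature across replicates", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 2000
    x <- cbind(signal = rnorm(n),
               matrix(rnorm(n * 5), n, 5,
                      dimnames = list(NULL, paste0("noise", 1:5))))
    t0 <- rexp(n, exp(x[, "signal"]) / 60)
    cc <- runif(n, 10, 200)
    sel <- rfe_cox_select(x, pmin(t0, cc), as.integer(t0 <= cc),
                          n_keep = 1)
    if (sel$kept == "signal") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("mrmr greedy selection matches an independent brute-force oracle", {
  set.seed(73)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 2] <- x[, 1] * 0.9 + rnorm(n, sd = 0.3)
  t0 <- rexp(n, exp(0.8 * x[, 1] - 0.5 * x[, 3]) / 50)
  cc <- runif(n, 10, 150)
  time <- pmin(t0, cc)
  event <- as.integer(t0 <= cc)

  sel <- mrmr_cindex_select(x, time, event, n_keep = 3)

  # independent greedy recomputation
  rel <- vapply(1:5, function(j) abs(c_index(x[, j], time, event) - 0.5),
                numeric(1))
  picked <- integer(0)
  for (step in 1:3) {
    cand <- setdiff(1:5, picked)
    sc <- vapply(cand, function(j) {
      if (!length(picked)) return(rel[j])
      rel[j] - mean(abs(stats::cor(x[, j], x[, picked])))
    }, numeric(1))
    picked <- c(picked, cand[which.max(sc)])
  }
  expect_equal(sel$kept, colnames(x)[picked])
  # first pick is the single max-relevance feature
  expect_equal(sel$kept[1], colnames(x)[which.max(rel)])
})

test_that("a duplicated column is never picked while positive scores remain", {
  set.seed(74)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  t0 <- rexp(n, exp(x[, 1] + 0.5 * x[, 2] + 0.3 * x[, 3]) / 50)
  cc <- runif(n, 10, 150)
  xx <- cbind(x, dup = x[, 1])
  sel <- mrmr_cindex_select(xx, pmin(t0, cc), as.integer(t0 <= cc),
                            n_keep = 4)
  expect_false("dup" %in% sel$kept)
})

test_that("elastic-net selection is deterministic and reports signed coefficients", {
  d <- make_ph_cohort(600, beta = 1, seed = 75)
  x <- cbind(d$x, matrix(rnorm(600 * 5), 600, 5,
                         dimnames = list(NULL, paste0("n", 1:5))))
  s1 <- coxnet_select(x, d$time, d$event, seed = 4)
  s2 <- coxnet_select(x, d$time, d$event, seed = 4)
  expect_identical(s1$stat, s2$stat)
  expect_identical(s1$l1_ratio, s2$l1_ratio)
  expect_true("a" %in% s1$kept)
  expect_gt(s1$stat[["a"]], 0)
  # sorted by decreasing magnitude
  expect_true(all(diff(abs(s1$stat)) <= 1e-12))
})

test_that("selection_table exports the feature/coefficient/type layout", {
  g <- make_clean_cohort(2500, seed = 76, target_event_rate = 0.3)
  feats <- setdiff(names(g$cohort), c("id", "time_months", "event"))
  pp <- preprocess_features(g$cohort[feats], method = "median")
  sel <- coxnet_select(pp$x, g$cohort$time_months, g$cohort$event,
                       seed = 1, l1_ratio_grid = 0.5)
  tab <- selection_table(sel, schema = attr(g$cohort, "schema"))
  expect_named(tab, c("feature", "statistic", "coefficient", "type"))
  expect_true(all(tab$type %in% c("Actionable", "Intrinsic")))
  age_row <- tab[tab$feature == "BLINE_AGE_AT_BASELINE", ]
  if (nrow(age_row)) expect_equal(age_row$type, "Intrinsic")
})

test_that("selection before modelling beats no selection on a wide cohort", {
  g <- make_clean_cohort(900, seed = 77, target_event_rate = 0.3)
  sp <- grid_spec(imputers = "median",
                  selectors = c("univariate_cox", "none"),
                  models = "MTLR", outer_k = 3, seed = 3)
  res <- run_grid(sp, g$cohort, tune = FALSE)
  agg <- res$aggregate
  with_sel <- agg$l1_hinge_mean[agg$selector == "univariate_cox"]
  without <- agg$l1_hinge_mean[agg$selector == "none"]
  expect_lt(with_sel, without)
})
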