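test_that("default schema has the documented block structure", {
  s <- default_feature_schema()
  expect_equal(nrow(s), 122)
  expect_equal(sum(s$actionable), 98)
  expect_equal(sum(!s$actionable), 24)
  expect_equal(as.integer(table(factor(s$block,
    levels = c("BLINE", "HLQ", "CDHQ1", "PYTPAQ")))),
    c(2L, 56L, 52L, 12L))
  expect_true(all(names(default_beta()) %in% s$name))
})

test_that("an empty request yields an empty cohort and truth", {
  g <- generate_cohort(generator_config(n = 0))
  expect_equal(nrow(g$cohort), 0)
  expect_length(g$truth$latent_time, 0)
})

test_that("the default cohort matches the target event rate and censor window", {
  g <- generate_cohort(generator_config(n = 18288, seed = 42))
  frac <- mean(g$cohort$event)
  expect_gte(frac, 0.028)
  expect_lte(frac, 0.038)
  cens_t <- g$cohort$time_months[g$cohort$event == 0]
  expect_true(all(cens_t >= 95 & cens_t <= 207))
  expect_true(all(g$cohort$time_months <= 207))
  expect_true(all(g$cohort$time_months > 0))
})

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n = 500, seed = 7)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_cohort(generator_config(n = 500, seed = 8))
  expect_false(identical(g1$cohort$time_months, g3$cohort$time_months))
})

test_that("event-rate calibration holds on average across seeds", {
  rates <- vapply(1:20, function(s) {
    mean(generate_cohort(generator_config(n = 18288, seed = s))$cohort$event)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.0331), 0.005)
})

test_that("a null-beta cohort's KM estimate tracks the closed-form Weibull", {
  cfg <- generator_config(
    n = 4000, seed = 11, beta = c(), baseline_shape = 1.5,
    baseline_scale = 400, target_event_rate = NULL,
    block_missing_rates = c(BLINE = 0, HLQ = 0, CDHQ1 = 0, PYTPAQ = 0),
    item_missing_rate = 0)
  g <- generate_cohort(cfg)
  km <- km_greenwood(g$cohort$time_months, g$cohort$event)
  for (t in c(30, 60, 90, 120, 150)) {
    s_true <- true_survival(g$truth, NULL, t)
    i <- max(which(km$time <= t))
    expect_gte(s_true, km$lower[i])
    expect_lte(s_true, km$upper[i])
  }
})

test_that("true_survival obeys its closed form and monotonicity", {
  tr <- structure(list(latent_time = numeric(0), censor_time = numeric(0),
                       eta = numeric(0), beta = c(),
                       baseline_shape = 1, baseline_scale = 100),
                  class = "truth_record")
  expect_equal(true_survival(tr, NULL, 0), 1.0)
  expect_equal(true_survival(tr, NULL, 100), exp(-1), tolerance = 1e-12)
  tr2 <- tr
  tr2$beta <- c(f1 = 0.5, f2 = -0.3)
  tr2$baseline_shape <- 1.7
  set.seed(3)
  for (r in 1:100) {
    x <- c(f1 = rnorm(1), f2 = rnorm(1))
    tt <- sort(runif(2, 0, 400))
    expect_gte(true_survival(tr2, x, tt[1]), true_survival(tr2, x, tt[2]))
  }
  expect_error(true_survival(tr2, c(zzz = 1, f1 = 0, f2 = 0), 10),
               "unknown feature")
})

test_that("latent event times agree with the survival oracle", {
  g <- make_clean_cohort(50000, seed = 21, target_event_rate = 0.10)
  for (t in c(100, 300, 600)) {
    emp <- mean(g$truth$latent_time <= t)
    lam <- g$truth$baseline_scale *
      exp(-g$truth$eta / g$truth$baseline_shape)
    model <- mean(1 - exp(-(t / lam)^g$truth$baseline_shape))
    expect_lt(abs(emp - model), 0.01)
  }
})

test_that("block and item missingness rates are respected", {
  cfg <- generator_config(
    n = 6000, seed = 5,
    block_missing_rates = c(BLINE = 0, HLQ = 0.1, CDHQ1 = 0.2,
                            PYTPAQ = 0.15),
    item_missing_rate = 0.03)
  g <- generate_cohort(cfg)
  s <- attr(g$cohort, "schema")
  for (blk in c("HLQ", "CDHQ1", "PYTPAQ")) {
    cols <- s$name[s$block == blk]
    frac <- mean(is.na(as.matrix(g$cohort[cols])))
    target <- cfg$block_missing_rates[[blk]] +
      (1 - cfg$block_missing_rates[[blk]]) * 0.03
    expect_lt(abs(frac - target), 0.02)
  }
})

test_that("summarize_cohort reproduces the count/percent panel", {
  tab <- data.frame(time_months = c(rep(100, 605), rep(150, 17683)),
                    event = c(rep(1L, 605), rep(0L, 17683)))
  sm <- summarize_cohort(tab, age_col = NULL)
  expect_equal(sm$pct_uncensored, 3.31)
  expect_equal(sm$n_uncensored, 605)

  all_cens <- data.frame(time_months = c(10, 20), event = c(0L, 0L))
  expect_equal(summarize_cohort(all_cens, age_col = NULL)$pct_uncensored,
               0.00)
  half <- data.frame(time_months = c(10, 20), event = c(1L, 0L))
  expect_equal(summarize_cohort(half, age_col = NULL)$pct_uncensored, 50.00)
})

test_that("cohort CSV round-trips with its schema sidecar", {
  g <- generate_cohort(generator_config(n = 40, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(g$cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back$time_months, g$cohort$time_months, tolerance = 1e-9)
  expect_equal(back$event, g$cohort$event)
  expect_equal(is.na(back$CDHQ1_SELENIUM_SPL),
               is.na(g$cohort$CDHQ1_SELENIUM_SPL))
  unlink(c(path, paste0(path, ".schema.json")))
})
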