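test_that("the mtlr gradient matches finite differences", {
  set.seed(51)
  d <- make_ph_cohort(60, seed = 51)
  fit <- fit_mtlr(d$x, d$time, d$event, C = 1)
  j0 <- vapply(seq_along(d$time), function(i) {
    if (d$event[i] == 1) sum(fit$tau < d$time[i])
    else sum(fit$tau <= d$time[i])
  }, numeric(1))
  obj <- bcaisd:::make_mtlr_objective(d$x, j0, d$event, fit$tau,
                                      C = 0.5, smoothness = 0.2)
  p0 <- rnorm(length(fit$tau) * 2) * 0.2
  ga <- obj$gr(p0)
  gn <- vapply(seq_along(p0), function(i) {
    e <- replace(rep(0, length(p0)), i, 1e-6)
    (obj$fn(p0 + e) - obj$fn(p0 - e)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(ga - gn)), 1e-5)
})

test_that("zero parameters give the uniform distribution over sequences", {
  d <- make_ph_cohort(100, seed = 52)
  fit <- fit_mtlr(d$x, d$time, d$event)
  fit$theta[] <- 0
  fit$bias[] <- 0
  S <- bcaisd:::mtlr_survival(fit, d$x[1:3, , drop = FALSE])
  m <- length(fit$tau)
  expected <- (m + 1 - seq_len(m)) / (m + 1)
  for (i in 1:3) expect_equal(unname(S[i, ]), expected, tolerance = 1e-12)
})

test_that("a covariate-free mtlr fit reproduces the Kaplan-Meier curve", {
  set.seed(53)
  n <- 2000
  t0 <- rexp(n, 1 / 80)
  cc <- runif(n, 30, 150)
  time <- pmin(t0, cc)
  event <- as.integer(t0 <= cc)
  fit <- fit_mtlr(matrix(0, n, 0), time, event)
  S <- bcaisd:::mtlr_survival(fit, matrix(0, n, 0))[1, ]
  km <- km_greenwood(time, event)
  km_at <- stats::approx(c(0, km$time), c(1, km$surv), xout = fit$tau,
                         method = "constant", rule = 2)$y
  expect_lt(max(abs(S - km_at)), 0.02)
})

test_that("the recorded optimization trace is non-increasing", {
  d <- make_ph_cohort(150, seed = 54)
  fit <- fit_mtlr(d$x, d$time, d$event, C = 1, trace = TRUE)
  expect_gte(length(fit$loss_trace), 1)
  expect_true(all(diff(fit$loss_trace) <= 1e-8))
})

test_that("predicted curves satisfy the ISD invariants and sign ordering", {
  d <- make_ph_cohort(400, beta = 1.2, seed = 55)
  fit <- fit_mtlr(d$x, d$time, d$event, C = 0.1)
  curves <- mtlr_predict(fit, d$x)
  for (cur in curves[1:50]) {
    expect_equal(cur$probs[1], 1)
    expect_true(all(diff(cur$probs) <= 1e-12))
    expect_true(all(cur$probs >= 0 & cur$probs <= 1))
  }
  # higher value of a deleterious feature -> lower curve everywhere
  hi <- mtlr_predict(fit, matrix(2, 1, 1))[[1]]
  lo <- mtlr_predict(fit, matrix(-2, 1, 1))[[1]]
  expect_true(all(hi$probs[-1] < lo$probs[-1]))
  expect_error(mtlr_predict(fit, matrix(0, 1, 3)), "columns")
})

test_that("mtlr curves can cross while cox curves cannot", {
  # construct an mtlr parameterization whose two subjects cross: one
  # feature accelerates early risk, the other late risk
  fit <- structure(list(
    tau = c(10, 20, 30, 40), theta = cbind(c(2, 0, 0, 0), c(0, 0, 0, 2)),
    bias = rep(0, 4), C = 1, smoothness = 0, columns = c("early", "late"),
    value = NA_real_, convergence = 0L, loss_trace = NULL),
    class = "mtlr_fit")
  x <- rbind(c(1.5, 0), c(0, 1.5))
  cur <- mtlr_predict(fit, x)
  diffs <- cur[[1]]$probs - cur[[2]]$probs
  expect_true(any(diffs[-1] > 0) && any(diffs[-1] < 0))

  d <- make_ph_cohort(500, beta = 1, seed = 56)
  cfit <- fit_cox_breslow_isd(d$x, d$time, d$event)
  curves <- predict_cox_isd(cfit, d$x[1:40, , drop = FALSE])
  for (i in 1:39) {
    dd <- curves[[i]]$probs - curves[[i + 1]]$probs
    expect_false(any(dd > 1e-12) && any(dd < -1e-12))
  }
})

test_that("mtlr curves need not reach zero at the horizon", {
  g <- make_clean_cohort(1500, seed = 57)          # ~3% events
  feats <- setdiff(names(g$cohort), c("id", "time_months", "event"))
  pp <- preprocess_features(g$cohort[feats], method = "median")
  keep <- names(default_beta())
  fit <- fit_mtlr(pp$x[, keep], g$cohort$time_months, g$cohort$event,
                  C = 1)
  curves <- mtlr_predict(fit, pp$x[1:20, keep])
  last_vals <- vapply(curves, function(cu) cu$probs[length(cu$probs)],
                      numeric(1))
  expect_true(all(last_vals > 0.5))
})

test_that("finetuning is the identity at zero epochs and reduces the loss", {
  d <- make_normal_cohort(400, seed = 58)
  fit <- fit_mtlr(d$x, d$time, d$event, C = 50)    # shrinkage-limited start
  f0 <- finetune_soft_l1(fit, d$x, d$time, d$event, epochs = 0)
  expect_identical(f0$bias, fit$bias)
  expect_identical(f0$theta, fit$theta)

  f1 <- finetune_soft_l1(fit, d$x, d$time, d$event, epochs = 100,
                         step = 1e-2)
  med <- function(f) resolve_median(
    vapply(mtlr_predict(f, d$x), median_event_time, numeric(1)),
    max(d$time))
  pre <- l1_hinge(med(fit), d$time, d$event)$mean
  post <- l1_hinge(med(f1), d$time, d$event)$mean
  expect_lte(post, pre)

  for (cu in mtlr_predict(f1, d$x[1:20, , drop = FALSE]))
    expect_true(all(diff(cu$probs) <= 1e-12))
})

test_that("mtlr fits serialize to json and back", {
  d <- make_ph_cohort(120, seed = 59)
  fit <- fit_mtlr(d$x, d$time, d$event, C = 1)
  path <- tempfile(fileext = ".json")
  mtlr_to_json(fit, path)
  back <- mtlr_from_json(path)
  expect_equal(back$tau, fit$tau)
  expect_equal(back$theta, fit$theta, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$bias, fit$bias, tolerance = 1e-12)
  unlink(path)
})
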