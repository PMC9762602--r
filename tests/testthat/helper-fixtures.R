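# shared fixture builders; everything is generated in code at test time

# small Weibull PH cohort with one standard-normal covariate
make_ph_cohort <- function(n, beta = 0.7, shape = 1, scale = 60,
                           cens = c(20, 150), seed = 1) {
  set.seed(seed)
  x <- cbind(a = stats::rnorm(n))
  lambda <- scale * exp(-beta * x[, 1] / shape)
  t0 <- lambda * stats::rexp(n)^(1 / shape)
  cc <- stats::runif(n, cens[1], cens[2])
  list(x = x, time = pmin(t0, cc), event = as.integer(t0 <= cc),
       latent = t0)
}

# symmetric (normal) event times, fully observed: median ~ mean
make_normal_cohort <- function(n, seed = 1, mu = 60, slope = 15, sd = 8) {
  set.seed(seed)
  x <- cbind(a = stats::rnorm(n))
  time <- pmax(1, stats::rnorm(n, mu + slope * x[, 1], sd))
  list(x = x, time = time, event = rep(1L, n))
}

# a default-schema cohort without missingness (for model-recovery tests)
make_clean_cohort <- function(n, seed = 1, target_event_rate = 0.0331) {
  cfg <- generator_config(
    n = n, seed = seed, target_event_rate = target_event_rate,
    block_missing_rates = c(BLINE = 0, HLQ = 0, CDHQ1 = 0, PYTPAQ = 0),
    item_missing_rate = 0)
  generate_cohort(cfg)
}

# naive O(n^2) concordance oracle, independent of the package implementation
brute_force_cindex <- function(pred, time, event) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 && time[i] < time[j]) {
        comp <- comp + 1
        if (pred[i] < pred[j]) conc <- conc + 1
        else if (pred[i] == pred[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}
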