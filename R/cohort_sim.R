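#' Generator configuration
#'
#' Bundles the knobs of the synthetic cohort generator. The defaults emulate
#' the cohort the pipeline is designed for: 18,288 women aged 35-70 at
#' recruitment, a 3.31% event (breast-cancer-onset) rate, administrative
#' censoring uniform on [95, 207] months, block-level and item-level
#' missingness, and a sparse Weibull proportional-hazards risk structure on
#' ten features.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config and seed.
#' @param schema Feature metadata table, see [default_feature_schema()].
#' @param beta Named vector of true log-hazard coefficients on the
#'   standardized feature scale; names must be numeric features of the
#'   schema. See [default_beta()].
#' @param baseline_shape Weibull shape of the event-time law (> 0). The
#'   default 1.5 gives a hazard increasing with time since recruitment.
#' @param baseline_scale Weibull scale in months; when
#'   \code{target_event_rate} is non-NULL this is only the starting point of
#'   the calibration and the calibrated value is returned in the truth
#'   record.
#' @param censor_window Two-vector \code{c(min, max)} of the administrative
#'   censoring window in months.
#' @param target_event_rate Fraction of uncensored subjects to calibrate the
#'   baseline scale to (by bisection); \code{NULL} keeps
#'   \code{baseline_scale} as given.
#' @param block_missing_rates Named fractions of subjects missing each whole
#'   questionnaire block.
#' @param item_missing_rate Fraction of remaining cells set missing
#'   completely at random.
#' @param confounder_strength Loading of a latent health-consciousness
#'   factor on diet/supplement/activity features; the same factor lowers the
#'   hazard, so a positive strength induces non-causal protective
#'   associations. 0 disables it.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n = 18288L,
                             seed = 1L,
                             schema = default_feature_schema(),
                             beta = default_beta(),
                             baseline_shape = 1.5,
                             baseline_scale = 1000,
                             censor_window = c(95, 207),
                             target_event_rate = 0.0331,
                             block_missing_rates = c(BLINE = 0, HLQ = 0,
                                                     CDHQ1 = 0.15,
                                                     PYTPAQ = 0.12),
                             item_missing_rate = 0.02,
                             confounder_strength = 0) {
  stopifnot(n >= 0, baseline_shape > 0, baseline_scale > 0,
            length(censor_window) == 2, censor_window[1] > 0,
            censor_window[1] <= censor_window[2],
            item_missing_rate >= 0, item_missing_rate <= 1,
            all(block_missing_rates >= 0), all(block_missing_rates <= 1))
  if (!is.null(target_event_rate))
    stopifnot(target_event_rate > 0, target_event_rate < 1)
  if (length(beta) && !all(names(beta) %in% schema$name))
    stop("beta names not in schema: ",
         paste(setdiff(names(beta), schema$name), collapse = ", "))
  structure(list(n = as.integer(n), seed = as.integer(seed), schema = schema,
                 beta = beta, baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censor_window = censor_window,
                 target_event_rate = target_event_rate,
                 block_missing_rates = block_missing_rates,
                 item_missing_rate = item_missing_rate,
                 confounder_strength = confounder_strength),
            class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' Draws feature values per the schema, computes a Weibull
#' proportional-hazards event time from the standardized values of the risk
#' features, applies uniform administrative censoring on the configured
#' window, calibrates the baseline scale by bisection so the realized event
#' rate matches \code{target_event_rate}, and finally knocks out whole
#' questionnaire blocks and individual items completely at random.
#'
#' The returned truth record keeps everything the observed table hides:
#' latent event times, censor draws, per-subject linear predictors, and the
#' calibrated Weibull parameters. It is the oracle for calibration and
#' recovery tests and is never an input to the modelling modules.
#'
#' @param config A [generator_config()].
#' @return A list with elements \code{cohort} (a \code{cohort_table}: a
#'   data.frame with \code{id}, \code{time_months}, \code{event} and one
#'   column per feature, plus the schema as attribute \code{"schema"}) and
#'   \code{truth} (a \code{truth_record}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  n <- config$n
  if (n == 0L) {
    cohort <- data.frame(id = integer(0), time_months = numeric(0),
                         event = integer(0))
    for (nm in schema$name) cohort[[nm]] <- numeric(0)
    attr(cohort, "schema") <- schema
    class(cohort) <- c("cohort_table", "data.frame")
    truth <- structure(list(latent_time = numeric(0),
                            censor_time = numeric(0), eta = numeric(0),
                            beta = config$beta,
                            baseline_shape = config$baseline_shape,
                            baseline_scale = config$baseline_scale),
                       class = "truth_record")
    return(list(cohort = cohort, truth = truth))
  }
  set.seed(config$seed)

  conf_factor <- stats::rnorm(n)
  conf_blocks <- c("CDHQ1", "PYTPAQ")

  raw <- vector("list", nrow(schema))
  names(raw) <- schema$name
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$dtype[i] == "numeric") {
      u <- stats::rnorm(n)
      if (config$confounder_strength > 0 && schema$block[i] %in% conf_blocks)
        u <- u + config$confounder_strength * conf_factor
      lo <- schema$min[i]; hi <- schema$max[i]
      if (hi - lo <= 1) {                      # binary-coded numeric
        raw[[nm]] <- as.numeric(u > stats::qnorm(0.6))
      } else {
        raw[[nm]] <- lo + (hi - lo) * stats::pnorm(u)
      }
    } else {
      lv <- schema_levels(schema, nm)
      raw[[nm]] <- sample(lv, n, replace = TRUE)
    }
  }

  ## linear predictor on standardized risk-feature values
  eta <- numeric(n)
  if (length(config$beta)) {
    for (nm in names(config$beta)) {
      v <- raw[[nm]]
      if (!is.numeric(v)) stop("risk feature must be numeric: ", nm)
      s <- stats::sd(v)
      z <- if (n < 2 || s == 0) rep(0, n) else (v - mean(v)) / s
      eta <- eta + config$beta[[nm]] * z
    }
  }
  if (config$confounder_strength > 0)
    eta <- eta - config$confounder_strength * conf_factor

  shape <- config$baseline_shape
  e_draw <- stats::rexp(n)                     # unit exponentials
  censor <- stats::runif(n, config$censor_window[1], config$censor_window[2])
  latent_for <- function(scale) {
    scale * exp(-eta / shape) * e_draw^(1 / shape)
  }

  scale <- config$baseline_scale
  if (!is.null(config$target_event_rate)) {
    rate_at <- function(s) mean(latent_for(s) <= censor)
    lo <- 1e-3; hi <- 1e8
    if (rate_at(lo) < config$target_event_rate ||
        rate_at(hi) > config$target_event_rate)
      stop(sprintf(
        "target event rate %.4f unreachable within scale bounds [%g, %g]",
        config$target_event_rate, lo, hi))
    for (it in seq_len(200)) {
      mid <- sqrt(lo * hi)
      r <- rate_at(mid)
      if (abs(r - config$target_event_rate) < 0.001) { lo <- hi <- mid; break }
      if (r > config$target_event_rate) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-12) break
    }
    scale <- sqrt(lo * hi)
  }

  latent <- latent_for(scale)
  event <- as.integer(latent <= censor)
  time <- pmin(latent, censor)

  cohort <- data.frame(id = seq_len(n), time_months = time, event = event)
  for (nm in schema$name) cohort[[nm]] <- raw[[nm]]

  ## missingness: whole blocks first, then items, both MCAR
  for (blk in names(config$block_missing_rates)) {
    rate <- config$block_missing_rates[[blk]]
    if (rate <= 0) next
    hit <- stats::runif(n) < rate
    for (nm in schema$name[schema$block == blk]) cohort[[nm]][hit] <- NA
  }
  if (config$item_missing_rate > 0) {
    for (nm in schema$name) {
      hit <- stats::runif(n) < config$item_missing_rate
      cohort[[nm]][hit] <- NA
    }
  }

  attr(cohort, "schema") <- schema
  class(cohort) <- c("cohort_table", "data.frame")
  truth <- structure(list(latent_time = latent, censor_time = censor,
                          eta = eta, beta = config$beta,
                          baseline_shape = shape, baseline_scale = scale),
                     class = "truth_record")
  list(cohort = cohort, truth = truth)
}

#' Closed-form survival of the generating law
#'
#' Under the generator's Weibull proportional-hazards law the survival
#' probability of a subject with standardized risk-feature values \code{x}
#' is \eqn{S(t|x) = \exp\{-(t/\lambda(x))^k\}} with
#' \eqn{\lambda(x) = \lambda_0 \exp(-x^\top\beta / k)}.
#'
#' @param truth A \code{truth_record} from [generate_cohort()].
#' @param subject_features Named numeric vector of standardized values for
#'   every risk feature in \code{truth$beta} (empty/NULL when beta is
#'   empty). Unknown names are an error.
#' @param t Time(s) in months, >= 0.
#' @return Survival probabilities, same length as \code{t}.
#' @export
true_survival <- function(truth, subject_features, t) {
  stopifnot(inherits(truth, "truth_record"), all(t >= 0))
  beta <- truth$beta
  x <- subject_features
  if (length(x)) {
    bad <- setdiff(names(x), names(beta))
    if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  }
  eta <- 0
  if (length(beta)) {
    miss <- setdiff(names(beta), names(x))
    if (length(miss)) stop("missing risk feature(s): ",
                           paste(miss, collapse = ", "))
    eta <- sum(beta * x[names(beta)])
  }
  lambda <- truth$baseline_scale * exp(-eta / truth$baseline_shape)
  exp(-(t / lambda)^truth$baseline_shape)
}

#' True survival curve of one generated subject
#'
#' Convenience oracle: evaluates the generating law at the subject's own
#' linear predictor (stored in the truth record) on a time grid and wraps
#' it as an [isd_curve()].
#'
#' @param truth A \code{truth_record}.
#' @param i Subject index.
#' @param times Strictly increasing positive time grid (months).
#' @return An \code{isd_curve}.
#' @export
true_isd_curve <- function(truth, i, times) {
  stopifnot(inherits(truth, "truth_record"), i >= 1,
            i <= length(truth$eta))
  lambda <- truth$baseline_scale * exp(-truth$eta[i] / truth$baseline_shape)
  isd_curve(times, exp(-(times / lambda)^truth$baseline_shape))
}

#' Cohort summary panel
#'
#' Counts and percentages of uncensored/censored subjects (percent rounded
#' to two decimals), age range and mean +/- sd of the designated age column,
#' and maximum and median follow-up, overall and within each censoring
#' class.
#'
#' @param cohort A \code{cohort_table} (or any data.frame with
#'   \code{time_months} and \code{event} columns).
#' @param age_col Name of the age column, or NULL to skip age statistics.
#' @return A list with components \code{n}, \code{n_uncensored},
#'   \code{n_censored}, \code{pct_uncensored}, \code{pct_censored},
#'   \code{age} (min/max/mean/sd by class, if requested),
#'   \code{max_followup} and \code{median_followup} (by class and overall).
#' @export
summarize_cohort <- function(cohort, age_col = "BLINE_AGE_AT_BASELINE") {
  stopifnot(nrow(cohort) > 0, all(c("time_months", "event") %in%
                                    names(cohort)))
  ev <- cohort$event == 1
  n <- nrow(cohort)
  out <- list(n = n, n_uncensored = sum(ev), n_censored = sum(!ev),
              pct_uncensored = round(100 * sum(ev) / n, 2),
              pct_censored = round(100 * sum(!ev) / n, 2))
  by_class <- function(f) {
    c(uncensored = if (any(ev)) f(cohort$time_months[ev]) else NA_real_,
      censored = if (any(!ev)) f(cohort$time_months[!ev]) else NA_real_,
      total = f(cohort$time_months))
  }
  out$max_followup <- by_class(max)
  out$median_followup <- by_class(stats::median)
  if (!is.null(age_col) && age_col %in% names(cohort)) {
    a <- cohort[[age_col]]
    grp <- function(idx) {
      v <- a[idx]; v <- v[!is.na(v)]
      if (!length(v)) return(c(min = NA, max = NA, mean = NA, sd = NA))
      c(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
    }
    out$age <- rbind(uncensored = grp(ev), censored = grp(!ev),
                     total = grp(rep(TRUE, n)))
  }
  out
}

#' Write / read a cohort as CSV with a JSON schema sidecar
#'
#' Columns: id, time_months, event, then features; empty cells are missing.
#'
#' @param cohort A \code{cohort_table}.
#' @param path CSV path; the sidecar goes to \code{<path>.schema.json}.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  schema <- attr(cohort, "schema")
  if (!is.null(schema))
    jsonlite::write_json(schema, paste0(path, ".schema.json"),
                         dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param check_range Validate non-missing values against the schema.
#' @export
read_cohort_csv <- function(path, check_range = TRUE) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = "")
  sidecar <- paste0(path, ".schema.json")
  schema <- NULL
  if (file.exists(sidecar)) {
    schema <- as.data.frame(jsonlite::read_json(sidecar,
                                                simplifyVector = TRUE))
    if (check_range) validate_cohort(cohort, schema)
    attr(cohort, "schema") <- schema
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

validate_cohort <- function(cohort, schema) {
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(cohort)) stop("missing feature column: ", nm)
    v <- cohort[[nm]]
    obs <- v[!is.na(v)]
    if (!length(obs)) next
    if (schema$dtype[i] == "numeric") {
      if (!is.numeric(obs)) stop("non-numeric values in ", nm)
      if (any(obs < schema$min[i] - 1e-9 | obs > schema$max[i] + 1e-9))
        stop("values out of range in ", nm)
    } else {
      lv <- schema_levels(schema, nm)
      if (!all(obs %in% lv)) stop("unknown category in ", nm)
    }
  }
  invisible(TRUE)
}
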