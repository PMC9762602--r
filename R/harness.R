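#' Stratified cross-validation splits
#'
#' Fold assignment stratified on both the censoring indicator and the
#' observed time: within each event class, subjects are ranked by time,
#' binned into quintiles (cells smaller than k are merged with their
#' neighbour), and each cell is dealt round-robin across the k folds in a
#' seeded random order. Folds therefore share both the event rate and the
#' time distribution of the whole sample.
#'
#' @param time Observed times.
#' @param event Event indicators.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per subject.
#' @export
stratified_splits <- function(time, event, k = 5, seed = 1) {
  n <- length(time)
  stopifnot(k <= n, length(event) == n)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cls in sort(unique(event))) {
    idx <- which(event == cls)
    ord <- idx[order(time[idx], idx)]
    nb <- max(1L, min(5L, floor(length(ord) / k)))
    bins <- split(ord, cut(seq_along(ord), breaks = nb, labels = FALSE))
    for (b in bins) {
      b <- sample(b)                         # seeded shuffle within cell
      fold[b] <- ((offset + seq_along(b) - 1L) %% k) + 1L
      offset <- offset + length(b)
    }
  }
  fold
}

#' Grid-search hyperparameter tuning by internal cross-validation
#'
#' Exhaustive search over a model's declared hyperparameter grid: each
#' setting is scored by internal k-fold cross-validation on the training
#' data, with the model's declared criterion (lowest mean L1-Hinge loss
#' or highest mean C-index). A single-point grid short-circuits without
#' inner fitting. Ties break toward the first grid entry.
#'
#' @param constructor A registry entry (see [default_model_registry()]).
#' @param x,time,event Training design matrix and outcome.
#' @param inner_k Internal folds.
#' @param seed Seed for the internal splits.
#' @return List: \code{hyper} (best setting), \code{score}, \code{metric}.
#' @export
tune_hyperparams <- function(constructor, x, time, event, inner_k = 5,
                             seed = 1) {
  grid <- constructor$hyper_grid
  if (is.null(grid) || length(grid) <= 1)
    return(list(hyper = if (length(grid)) grid[[1]] else list(),
                score = NA_real_, metric = constructor$tune_metric))
  metric <- constructor$tune_metric
  fold <- stratified_splits(time, event, k = inner_k, seed = seed)
  scores <- vapply(grid, function(h) {
    vals <- vapply(seq_len(inner_k), function(f) {
      tr <- fold != f
      te <- !tr
      val <- tryCatch({
        fit <- constructor$fit(x[tr, , drop = FALSE], time[tr], event[tr],
                               h)
        grid_t <- eval_grid_times(time[tr])
        curves <- constructor$predict(fit, x[te, , drop = FALSE], grid_t)
        med <- resolve_median(
          vapply(curves, median_event_time, numeric(1)), max(time[tr]))
        if (metric == "l1_hinge")
          l1_hinge(med, time[te], event[te])$mean
        else c_index(med, time[te], event[te])
      }, error = function(e) NA_real_)
      val
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  if (all(is.na(scores))) stop("all inner fits failed for every setting")
  best <- if (metric == "l1_hinge") which.min(scores) else
    which.max(scores)
  list(hyper = grid[[best]], score = scores[best], metric = metric)
}

eval_grid_times <- function(time) {
  qs <- unique(stats::quantile(time, probs = seq(0.05, 1, by = 0.05),
                               names = FALSE))
  qs[qs > 0]
}

selector_registry <- function() {
  list(
    univariate_cox = function(x, time, event, seed)
      univariate_cox_select(x, time, event),
    rfe_cox = function(x, time, event, seed)
      rfe_cox_select(x, time, event, n_keep = min(10, ncol(x))),
    mrmr_cindex = function(x, time, event, seed)
      mrmr_cindex_select(x, time, event, n_keep = min(10, ncol(x))),
    coxnet = function(x, time, event, seed)
      coxnet_select(x, time, event, seed = seed),
    none = function(x, time, event, seed) select_none(x, time, event)
  )
}

#' Benchmark grid specification
#'
#' @param imputers Imputation method names (default the three of the
#'   pipeline).
#' @param selectors Feature-selection arm names (four methods plus the
#'   passthrough).
#' @param models Registry model names (default the nine-model roster).
#' @param outer_k,inner_k Outer and internal fold counts.
#' @param seed Master seed.
#' @return Object of class \code{grid_spec}. The default roster enumerates
#'   3 x 5 x 9 = 135 configurations.
#' @export
grid_spec <- function(imputers = c("median", "knn", "mice"),
                      selectors = c("univariate_cox", "rfe_cox",
                                    "mrmr_cindex", "coxnet", "none"),
                      models = names(default_model_registry()),
                      outer_k = 5, inner_k = 5, seed = 1) {
  structure(list(imputers = imputers, selectors = selectors,
                 models = models, outer_k = outer_k, inner_k = inner_k,
                 seed = seed), class = "grid_spec")
}

#' Enumerate the configurations of a grid
#'
#' @param spec A [grid_spec()].
#' @return data.frame with one row per (imputer, selector, model)
#'   configuration and a \code{config_id} key.
#' @export
enumerate_grid <- function(spec) {
  g <- expand.grid(model = spec$models, selector = spec$selectors,
                   imputer = spec$imputers, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("imputer", "selector", "model")]
  g$config_id <- paste(g$imputer, g$selector, g$model, sep = "+")
  g
}

#' Run the benchmark grid
#'
#' For every (imputer, selector, model) configuration and outer fold:
#' imputation and the one-hot/z-score transform are fitted on the training
#' fold only and applied to the test fold; feature selection runs on the
#' training design matrix; hyperparameters are tuned by internal CV on the
#' training fold; the model is fitted and its test-fold ISD curves scored
#' with the full metric panel. Adapter slots without a registered
#' constructor produce explicit skip records, never silent gaps, and
#' per-configuration failures are isolated and logged while the grid
#' continues.
#'
#' @param spec A [grid_spec()].
#' @param cohort A \code{cohort_table}.
#' @param registry Model registry (default [default_model_registry()]).
#' @param tune Run internal hyperparameter search (disable for speed on
#'   small studies; the first grid entry is then used).
#' @return Object of class \code{grid_result}: \code{folds} (one row per
#'   config x fold, with metrics or a skip/error status) and
#'   \code{aggregate} (mean +/- sd over scored folds per config).
#' @export
run_grid <- function(spec, cohort, registry = default_model_registry(),
                     tune = TRUE) {
  stopifnot(inherits(spec, "grid_spec"))
  configs <- enumerate_grid(spec)
  feats <- setdiff(names(cohort), c("id", "time_months", "event"))
  time <- cohort$time_months
  event <- cohort$event
  fold <- stratified_splits(time, event, k = spec$outer_k,
                            seed = spec$seed)
  sel_reg <- selector_registry()

  rows <- list()
  ## cache per (imputer, fold): the design matrices are selector- and
  ## model-independent
  pp_cache <- new.env(parent = emptyenv())
  sel_cache <- new.env(parent = emptyenv())
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    constructor <- registry[[cfg$model]]
    for (f in seq_len(spec$outer_k)) {
      base <- list(config_id = cfg$config_id, imputer = cfg$imputer,
                   selector = cfg$selector, model = cfg$model, fold = f)
      if (is.null(constructor)) {
        rows[[length(rows) + 1]] <- c(base, list(
          status = "skipped: no adapter registered",
          l1_hinge = NA_real_, c_index = NA_real_, dcal_p = NA_real_,
          d_calibrated = NA))
        next
      }
      res <- tryCatch({
        tr <- which(fold != f)
        key <- paste(cfg$imputer, f)
        if (!exists(key, envir = pp_cache)) {
          pp <- preprocess_features(cohort[feats], method = cfg$imputer,
                                    seed = spec$seed, fitted_on = tr)
          assign(key, pp, envir = pp_cache)
        }
        pp <- get(key, envir = pp_cache)
        skey <- paste(cfg$imputer, cfg$selector, f)
        if (!exists(skey, envir = sel_cache)) {
          sel <- sel_reg[[cfg$selector]](pp$x[tr, , drop = FALSE],
                                         time[tr], event[tr],
                                         seed = spec$seed)
          assign(skey, sel, envir = sel_cache)
        }
        sel <- get(skey, envir = sel_cache)
        kept <- sel$kept
        if (!length(kept)) stop("selector kept zero features")
        xtr <- pp$x[tr, kept, drop = FALSE]
        xte <- pp$x[-tr, kept, drop = FALSE]
        hyper <- if (tune)
          tune_hyperparams(constructor, xtr, time[tr], event[tr],
                           inner_k = spec$inner_k, seed = spec$seed)$hyper
        else constructor$hyper_grid[[1]]
        fit <- constructor$fit(xtr, time[tr], event[tr], hyper)
        curves <- constructor$predict(fit, xte, eval_grid_times(time[tr]))
        rep <- metric_report(curves, time[-tr], event[-tr])
        c(base, list(status = "ok", l1_hinge = rep$l1_hinge,
                     c_index = rep$c_index, dcal_p = rep$dcal_p,
                     d_calibrated = rep$d_calibrated))
      }, error = function(e) {
        c(base, list(status = paste("error:", conditionMessage(e)),
                     l1_hinge = NA_real_, c_index = NA_real_,
                     dcal_p = NA_real_, d_calibrated = NA))
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  folds <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  agg <- aggregate_grid(folds)
  structure(list(folds = folds, aggregate = agg, spec = spec),
            class = "grid_result")
}

aggregate_grid <- function(folds) {
  ids <- unique(folds$config_id)
  do.call(rbind, lapply(ids, function(id) {
    sub <- folds[folds$config_id == id, ]
    ok <- sub$status == "ok"
    data.frame(
      config_id = id, imputer = sub$imputer[1], selector = sub$selector[1],
      model = sub$model[1], n_folds = nrow(sub), n_scored = sum(ok),
      l1_hinge_mean = if (any(ok)) mean(sub$l1_hinge[ok]) else NA_real_,
      l1_hinge_sd = if (sum(ok) > 1) stats::sd(sub$l1_hinge[ok])
                    else NA_real_,
      c_index_mean = if (any(ok)) mean(sub$c_index[ok]) else NA_real_,
      c_index_sd = if (sum(ok) > 1) stats::sd(sub$c_index[ok])
                   else NA_real_,
      all_d_calibrated = if (any(ok)) all(sub$d_calibrated[ok]) else NA,
      status = if (all(ok)) "ok" else sub$status[!ok][1],
      stringsAsFactors = FALSE)
  }))
}

#' Select the best configuration of a grid result
#'
#' The selection rule of the benchmark: restrict to configurations that
#' were D-calibrated in every scored fold (and fully scored), pick the one
#' with the lowest mean L1-Hinge loss, and break ties (within 1e-9 months)
#' by the highest mean C-index. When no configuration is D-calibrated the
#' result is \code{NULL} with a diagnostic attribute listing each
#' configuration's failure.
#'
#' @param result A \code{grid_result}.
#' @return The winning \code{config_id}, or \code{NA} (with a
#'   \code{"diagnostic"} attribute listing per-configuration failures)
#'   when nothing qualifies.
#' @export
select_best_model <- function(result) {
  agg <- result$aggregate
  ok <- agg$n_scored == agg$n_folds & !is.na(agg$all_d_calibrated) &
    agg$all_d_calibrated
  if (!any(ok)) {
    diag <- agg[, c("config_id", "n_scored", "all_d_calibrated", "status")]
    out <- NA_character_
    attr(out, "diagnostic") <- diag
    return(out)
  }
  cand <- agg[ok, ]
  best_loss <- min(cand$l1_hinge_mean)
  tied <- cand[cand$l1_hinge_mean <= best_loss + 1e-9, ]
  tied$config_id[which.max(tied$c_index_mean)]
}

#' Fit one full pipeline and keep it for prediction on raw rows
#'
#' Fits imputation + encoding on the whole supplied cohort, runs one
#' feature-selection arm, tunes and fits one model, and returns a pipeline
#' object whose [predict_pipeline()] maps raw feature rows (missing values
#' allowed) to ISD curves. This is the object the counterfactual
#' machinery edits features through: the edit happens on the raw scale and
#' is re-passed through the fitted transform.
#'
#' @param cohort A \code{cohort_table}.
#' @param imputer,selector,model Arm names.
#' @param registry Model registry.
#' @param seed Seed.
#' @param tune Tune hyperparameters by internal CV.
#' @return Object of class \code{isd_pipeline}.
#' @export
fit_pipeline <- function(cohort, imputer = "mice", selector = "coxnet",
                         model = "MTLR",
                         registry = default_model_registry(), seed = 1,
                         tune = FALSE) {
  feats <- setdiff(names(cohort), c("id", "time_months", "event"))
  time <- cohort$time_months
  event <- cohort$event
  pp <- preprocess_features(cohort[feats], method = imputer, seed = seed)
  sel <- selector_registry()[[selector]](pp$x, time, event, seed = seed)
  if (!length(sel$kept)) stop("selector kept zero features")
  xk <- pp$x[, sel$kept, drop = FALSE]
  constructor <- registry[[model]]
  if (is.null(constructor)) stop("no adapter registered for ", model)
  hyper <- if (tune)
    tune_hyperparams(constructor, xk, time, event, seed = seed)$hyper
  else constructor$hyper_grid[[1]]
  fit <- constructor$fit(xk, time, event, hyper)
  structure(list(imputer = imputer, selector = selector, model = model,
                 impute_stats = attr(impute_median(cohort[feats]),
                                     "impute_stats"),
                 transform = pp$transform, kept = sel$kept,
                 selection = sel, fit = fit, constructor = constructor,
                 grid_times = eval_grid_times(time), seed = seed),
            class = "isd_pipeline")
}

#' @rdname fit_pipeline
#' @param pipeline A fitted \code{isd_pipeline}.
#' @param new_rows Data.frame of raw feature rows (extra columns such as
#'   id/time/event are ignored; missing cells are median/mode-filled with
#'   the training statistics).
#' @return List of [isd_curve()]s.
#' @export
predict_pipeline <- function(pipeline, new_rows) {
  stopifnot(inherits(pipeline, "isd_pipeline"))
  feats <- names(pipeline$transform$params)
  rows <- new_rows[, feats, drop = FALSE]
  rows <- impute_median(rows, stats = pipeline$impute_stats)
  x <- apply_transform(pipeline$transform, rows)
  x <- x[, pipeline$kept, drop = FALSE]
  pipeline$constructor$predict(pipeline$fit, x, pipeline$grid_times)
}
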