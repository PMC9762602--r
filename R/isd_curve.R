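#' Individual survival distribution curve
#'
#' An ISD is a subject-specific survival (cancer-free probability) function:
#' a strictly increasing time grid with non-increasing probabilities in
#' [0, 1], anchored at S(0) = 1. Off-grid times are linearly interpolated;
#' beyond the last grid point the tail rule applies: with
#' \code{"linear_last_segment"} the final segment's slope is extended
#' (clamped to [0, 1]), with \code{"none"} the last value is carried
#' forward.
#'
#' @param times Positive, strictly increasing time grid in months (0 is
#'   prepended automatically if absent).
#' @param probs Survival probabilities at \code{times} (a leading 1 is
#'   prepended alongside time 0).
#' @param tail_rule \code{"linear_last_segment"} or \code{"none"}.
#' @return An object of class \code{isd_curve}.
#' @export
isd_curve <- function(times, probs, tail_rule = "linear_last_segment") {
  stopifnot(length(times) == length(probs), length(times) >= 1,
            tail_rule %in% c("linear_last_segment", "none"))
  if (times[1] != 0) {
    times <- c(0, times)
    probs <- c(1, probs)
  }
  probs <- pmin(pmax(probs, 0), 1)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(diff(probs) > 1e-9)) stop("probs must be non-increasing")
  if (abs(probs[1] - 1) > 1e-9) stop("S(0) must be 1")
  probs <- cummin(probs)
  structure(list(times = as.numeric(times), probs = as.numeric(probs),
                 tail_rule = tail_rule), class = "isd_curve")
}

#' @export
print.isd_curve <- function(x, ...) {
  cat(sprintf("isd_curve: %d grid points on [0, %g] months, S(end) = %.3f\n",
              length(x$times), max(x$times), x$probs[length(x$probs)]))
  invisible(x)
}

#' Survival probability at a time
#'
#' Linear interpolation on the curve's grid; beyond the grid the curve's
#' tail rule applies; the result is clamped to [0, 1].
#'
#' @param curve An [isd_curve()].
#' @param t Time(s) in months, >= 0.
#' @return Probabilities, same length as \code{t}.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "isd_curve"))
  if (any(t < 0)) stop("t must be non-negative")
  tm <- curve$times; pr <- curve$probs
  k <- length(tm)
  out <- stats::approx(tm, pr, xout = pmin(t, tm[k]), method = "linear",
                       ties = "ordered")$y
  beyond <- t > tm[k]
  if (any(beyond) && curve$tail_rule == "linear_last_segment" && k >= 2) {
    slope <- (pr[k] - pr[k - 1]) / (tm[k] - tm[k - 1])
    out[beyond] <- pr[k] + slope * (t[beyond] - tm[k])
  }
  pmin(pmax(out, 0), 1)
}

#' Median predicted event time
#'
#' The first time at which the curve crosses survival 0.5, by linear
#' interpolation. If the curve ends above 0.5 and its tail rule is
#' \code{"linear_last_segment"}, the final segment's slope is extended
#' until it crosses; a flat tail (or tail rule \code{"none"}) yields the
#' beyond-horizon sentinel \code{Inf}.
#'
#' @param curve An [isd_curve()].
#' @return Months, or \code{Inf} when the curve never reaches 0.5.
#' @export
median_event_time <- function(curve) {
  stopifnot(inherits(curve, "isd_curve"))
  tm <- curve$times; pr <- curve$probs
  k <- length(tm)
  idx <- which(pr <= 0.5)
  if (length(idx)) {
    j <- idx[1]
    if (pr[j] == 0.5) return(tm[j])
    # crossing inside segment (j-1, j); j >= 2 because pr[1] = 1
    t0 <- tm[j - 1]; t1 <- tm[j]; p0 <- pr[j - 1]; p1 <- pr[j]
    return(t0 + (p0 - 0.5) / (p0 - p1) * (t1 - t0))
  }
  if (curve$tail_rule != "linear_last_segment" || k < 2) return(Inf)
  slope <- (pr[k] - pr[k - 1]) / (tm[k] - tm[k - 1])
  if (slope >= 0) return(Inf)
  tm[k] + (pr[k] - 0.5) / (-slope)
}

#' Attained age after a number of months
#'
#' Converts months since recruitment to an attained age in whole years,
#' rounding up: a woman recruited at 62 who reaches 267 months is in her
#' 85th year.
#'
#' @param age_at_recruitment Age in years at recruitment (>= 0).
#' @param months_from_recruitment Months since recruitment (>= 0).
#' @return Integer years.
#' @export
months_to_age <- function(age_at_recruitment, months_from_recruitment) {
  stopifnot(all(age_at_recruitment >= 0), all(months_from_recruitment >= 0))
  as.integer(ceiling(age_at_recruitment + months_from_recruitment / 12))
}

#' Counterfactual single-feature intervention
#'
#' Recomputes a subject's predicted median event time after editing one
#' actionable feature on the raw scale, keeping every other feature
#' unchanged, and reports the gain (or loss) in cancer-free months.
#' Editing an intrinsic feature (age, menarche age, medical history, ...)
#' is refused: interventions are only meaningful on features a participant
#' can modify.
#'
#' The predictor can be a fitted pipeline (see [fit_pipeline()]) or any
#' function mapping a one-row raw feature data.frame to an
#' [isd_curve()].
#'
#' @param model A \code{isd_pipeline} or a function \code{raw_row ->
#'   isd_curve}.
#' @param metadata Feature schema (see [default_feature_schema()]).
#' @param x One-row data.frame of raw feature values.
#' @param feature Name of the feature to edit; must be actionable.
#' @param new_value Replacement value, within the feature's admissible
#'   range.
#' @param age_at_recruitment Optional recruitment age; when given, attained
#'   ages for both medians are reported.
#' @return A list of class \code{intervention_report}: feature, old/new
#'   value, baseline and counterfactual predicted medians (months), delta
#'   (counterfactual - baseline), and optional attained ages.
#' @export
counterfactual_delta <- function(model, metadata, x, feature, new_value,
                                 age_at_recruitment = NULL) {
  row <- metadata[metadata$name == feature, ]
  if (nrow(row) != 1) stop("unknown feature: ", feature)
  if (!row$actionable)
    stop("refusing to edit intrinsic feature '", feature,
         "': interventions apply to actionable lifestyle features only")
  if (row$dtype == "numeric") {
    if (!is.na(row$min) && (new_value < row$min || new_value > row$max))
      stop(sprintf("new value %g outside admissible range [%g, %g]",
                   new_value, row$min, row$max))
  } else {
    lv <- schema_levels(metadata, feature)
    if (!new_value %in% lv)
      stop("new value not an admissible category of ", feature)
  }
  predict_one <- if (is.function(model)) model else
    function(r) predict_pipeline(model, r)[[1]]
  base_curve <- predict_one(x)
  x2 <- x
  x2[[feature]] <- new_value
  cf_curve <- predict_one(x2)
  base_med <- median_event_time(base_curve)
  cf_med <- median_event_time(cf_curve)
  rep <- list(feature = feature, old_value = x[[feature]],
              new_value = new_value, baseline_median = base_med,
              counterfactual_median = cf_med, delta = cf_med - base_med)
  if (!is.null(age_at_recruitment) && is.finite(base_med) &&
      is.finite(cf_med)) {
    rep$baseline_attained_age <- months_to_age(age_at_recruitment, base_med)
    rep$counterfactual_attained_age <- months_to_age(age_at_recruitment,
                                                     cf_med)
  }
  class(rep) <- "intervention_report"
  rep
}

#' @export
print.intervention_report <- function(x, ...) {
  cat(sprintf("Intervention on %s: %s -> %s\n", x$feature,
              format(x$old_value), format(x$new_value)))
  cat(sprintf("  predicted median: %.1f -> %.1f months (delta %+.1f)\n",
              x$baseline_median, x$counterfactual_median, x$delta))
  if (!is.null(x$baseline_attained_age))
    cat(sprintf("  attained age: %d -> %d years\n",
                x$baseline_attained_age, x$counterfactual_attained_age))
  invisible(x)
}

#' Export curves as long-format CSV
#'
#' @param curves List of [isd_curve()] objects.
#' @param ids Subject identifiers (defaults to list position).
#' @param path Output CSV path.
#' @export
write_curves_csv <- function(curves, path, ids = seq_along(curves)) {
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(id = ids[i], time_months = curves[[i]]$times,
               survival_prob = curves[[i]]$probs)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
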