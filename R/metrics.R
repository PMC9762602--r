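#' Censoring-aware L1-Hinge loss
#'
#' For an uncensored subject the loss is the absolute difference between
#' the predicted median event time and the observed event time. For a
#' censored subject the observed time is only a lower bound, so a
#' prediction later than the censoring time incurs no loss and an earlier
#' one is charged the shortfall: \code{max(0, c - pred)}.
#'
#' Beyond-horizon predictions (\code{Inf} medians) must be resolved by the
#' caller; [resolve_median()] applies the package's cap.
#'
#' @param pred_median Predicted median event times (months), finite.
#' @param time Observed event/censoring times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return List with \code{loss} (per subject) and \code{mean}.
#' @export
l1_hinge <- function(pred_median, time, event) {
  stopifnot(length(pred_median) == length(time),
            length(time) == length(event))
  if (any(time < 0) || any(pred_median < 0)) stop("negative times")
  if (any(!is.finite(pred_median)))
    stop("non-finite predicted medians; resolve beyond-horizon ",
         "sentinels first (see resolve_median)")
  loss <- ifelse(event == 1, abs(pred_median - time),
                 pmax(0, time - pred_median))
  list(loss = loss, mean = mean(loss))
}

#' Resolve beyond-horizon medians to a finite value
#'
#' Curves that never cross survival 0.5 -- even after tail extrapolation --
#' have no finite median; for loss computation they are capped at a
#' multiple of the maximum observed follow-up.
#'
#' @param pred_median Medians, possibly \code{Inf}.
#' @param max_followup Maximum observed follow-up (months).
#' @param horizon_multiple Cap = \code{horizon_multiple * max_followup}.
#' @return Finite medians.
#' @export
resolve_median <- function(pred_median, max_followup, horizon_multiple = 10) {
  pmin(pred_median, horizon_multiple * max_followup)
}

#' Time-invariant concordance index
#'
#' The fraction of comparable subject pairs whose predicted (median) event
#' times are ordered like their observed times. A pair (i, j) is comparable
#' when subject i has an event strictly before subject j's observed time
#' (j may be censored or a later event); pairs tied on event time are not
#' comparable. Tied predictions receive half credit. The model's risk score
#' is the negative of its predicted median, so "concordant" means the
#' earlier event got the earlier prediction.
#'
#' @param pred_median Predicted median event times.
#' @param time Observed times.
#' @param event Event indicators.
#' @return Concordance in [0, 1].
#' @export
c_index <- function(pred_median, time, event) {
  stopifnot(length(pred_median) == length(time),
            length(time) == length(event))
  n <- length(time)
  conc <- 0
  comp <- 0
  for (i in which(event == 1)) {
    cmp <- time[i] < time
    comp <- comp + sum(cmp)
    conc <- conc + sum(pred_median[i] < pred_median[cmp]) +
      0.5 * sum(pred_median[i] == pred_median[cmp])
  }
  if (comp == 0) stop("no comparable pairs (no event strictly precedes ",
                      "another subject's observed time)")
  conc / comp
}

#' D-calibration
#'
#' Goodness-of-fit test that the predicted survival probabilities evaluated
#' at the observed times are uniform on [0, 1]. Each uncensored subject
#' contributes weight 1 to the probability bin containing
#' \eqn{p_i = S_i(t_i)}; a censored subject with \eqn{p_i = S_i(c_i) > 0}
#' knows only that her event probability lies in \eqn{[0, p_i]}, assumed
#' uniform under the model, so she spreads weight
#' \eqn{\max(0, \min(p_i, u) - l)/p_i} over each bin [l, u); with
#' \eqn{p_i = 0} the whole weight goes to the lowest bin. The statistic is
#' Pearson's chi-square of the bin weights against n/B, referred to a
#' chi-square with B - 1 degrees of freedom (Hosmer-Lemeshow); the model is
#' declared D-calibrated when p > 0.05. Bins are closed on the upper end: a
#' probability exactly on an interior edge counts to the lower bin.
#'
#' @param curves List of [isd_curve()] objects, one per subject.
#' @param time Observed times.
#' @param event Event indicators.
#' @param B Number of equal probability bins (>= 2; the convention is 10).
#' @return List: \code{bin_weights} (length B, lowest probability bin
#'   first), \code{statistic}, \code{p_value}, \code{d_calibrated}, \code{n}.
#' @export
d_calibration <- function(curves, time, event, B = 10) {
  stopifnot(B >= 2, length(curves) == length(time),
            length(time) == length(event))
  n <- length(time)
  w <- numeric(B)
  edges <- seq(0, 1, length.out = B + 1)
  for (i in seq_len(n)) {
    p <- survival_at(curves[[i]], time[i])
    if (event[i] == 1) {
      b <- bin_of(p, B)
      w[b] <- w[b] + 1
    } else if (p <= 0) {
      w[1] <- w[1] + 1
    } else {
      lo <- edges[-(B + 1)]
      hi <- edges[-1]
      w <- w + pmax(0, pmin(p, hi) - lo) / p
    }
  }
  expected <- n / B
  statistic <- sum((w - expected)^2 / expected)
  p_value <- stats::pchisq(statistic, df = B - 1, lower.tail = FALSE)
  list(bin_weights = w, statistic = statistic, p_value = p_value,
       d_calibrated = p_value > 0.05, n = n)
}

# bin index with upper-closed edges: p in ((b-1)/B, b/B] -> b; p = 0 -> 1
bin_of <- function(p, B) {
  b <- ceiling(p * B)
  min(max(b, 1L), B)
}

#' Kaplan-Meier estimate with Greenwood confidence bands
#'
#' Product-limit estimator with the Greenwood variance
#' \eqn{\hat S(t)^2 \sum_{t_i \le t} d_i / \{n_i(n_i - d_i)\}} and
#' pointwise confidence intervals on the log(-log) scale, clamped to
#' [0, 1].
#'
#' @param time Observed times.
#' @param event Event indicators.
#' @param level Confidence level (default 0.95).
#' @return List of class \code{km_estimate}: \code{time}, \code{surv},
#'   \code{greenwood_var}, \code{lower}, \code{upper}, \code{level}.
#' @export
km_greenwood <- function(time, event, level = 0.95) {
  stopifnot(length(time) > 0, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = level)
  gw <- fit$surv^2 * cumsum(ifelse(fit$n.risk > fit$n.event,
                                   fit$n.event /
                                     (fit$n.risk *
                                        (fit$n.risk - fit$n.event)),
                                   0))
  lower <- ifelse(is.na(fit$lower), 0, fit$lower)
  upper <- ifelse(is.na(fit$upper), 1, fit$upper)
  # degenerate tail: S = 0 has zero variance, CI collapses
  lower[fit$surv == 0] <- 0
  upper[fit$surv == 0] <- 0
  upper[fit$surv == 1] <- 1
  lower2 <- pmin(lower, fit$surv)
  upper2 <- pmax(upper, fit$surv)
  structure(list(time = fit$time, surv = fit$surv, greenwood_var = gw,
                 lower = pmax(lower2, 0), upper = pmin(upper2, 1),
                 level = level),
            class = "km_estimate")
}

#' Score a model's predictions on one evaluation set
#'
#' Computes the full metric panel -- mean L1-Hinge loss, time-invariant
#' C-index and D-calibration -- from predicted curves and observed
#' outcomes.
#'
#' @param curves List of [isd_curve()] predictions.
#' @param time Observed times.
#' @param event Event indicators.
#' @param B D-calibration bins.
#' @param horizon_multiple Cap for beyond-horizon medians, as a multiple of
#'   the maximum observed follow-up.
#' @return List of class \code{metric_report}.
#' @export
metric_report <- function(curves, time, event, B = 10,
                          horizon_multiple = 10) {
  med <- vapply(curves, median_event_time, numeric(1))
  med <- resolve_median(med, max(time), horizon_multiple)
  l1 <- l1_hinge(med, time, event)
  ci <- c_index(med, time, event)
  dc <- d_calibration(curves, time, event, B = B)
  structure(list(l1_hinge = l1$mean, c_index = ci,
                 dcal_bin_weights = dc$bin_weights,
                 dcal_statistic = dc$statistic, dcal_p = dc$p_value,
                 d_calibrated = dc$d_calibrated,
                 n = length(time), events = sum(event == 1)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report: n = %d (%d events)\n  L1-Hinge %.3f months | C-index %.3f | D-cal p = %.3f (%s)\n",
    x$n, x$events, x$l1_hinge, x$c_index, x$dcal_p,
    if (x$d_calibrated) "calibrated" else "NOT calibrated"))
  invisible(x)
}
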