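#' Median / mode imputation
#'
#' Fills missing numeric cells with the median, and missing categorical
#' cells with the mode, of the fitting set. Observed values are never
#' touched, and the transform is learned on the fitting rows only so it can
#' be reused on held-out folds without leakage.
#'
#' @param table Data.frame of feature columns (may contain NA).
#' @param fitted_on Row indices to learn the statistics from (default: all
#'   rows of \code{table}).
#' @param stats Optional pre-fitted statistics (as returned in the
#'   \code{"impute_stats"} attribute) to apply instead of fitting.
#' @return The completed data.frame, with the fitted statistics in
#'   attribute \code{"impute_stats"}.
#' @export
impute_median <- function(table, fitted_on = seq_len(nrow(table)),
                          stats = NULL) {
  if (is.null(stats)) {
    stats <- lapply(names(table), function(nm) {
      v <- table[[nm]][fitted_on]
      obs <- v[!is.na(v)]
      if (!length(obs)) stop("column all-missing in fitting set: ", nm)
      if (is.numeric(v)) stats::median(obs)
      else names(sort(table(obs), decreasing = TRUE))[1]
    })
    names(stats) <- names(table)
  }
  for (nm in names(table)) {
    miss <- is.na(table[[nm]])
    if (any(miss)) table[[nm]][miss] <- stats[[nm]]
  }
  attr(table, "impute_stats") <- stats
  table
}

#' K-nearest-neighbour imputation
#'
#' A missing cell of subject p, feature f, is replaced by the mean of f
#' (post one-hot for categorical f, then decoded by majority) over p's k
#' nearest donors among the fitting rows observed on f. Distance is
#' Euclidean over the remaining features, missing-aware: the mean squared
#' difference over co-observed coordinates (categorical coordinates
#' contribute 0/1 disagreement), so subjects with different missingness
#' patterns remain comparable. Ties in distance are broken by row order.
#'
#' @inheritParams impute_median
#' @param k Number of donors (>= 1; the field default is 2).
#' @return Completed data.frame.
#' @export
impute_knn <- function(table, k = 2, fitted_on = seq_len(nrow(table))) {
  stopifnot(k >= 1)
  p <- ncol(table)
  ## numeric coding for distances: z-score numerics on fitting rows,
  ## categoricals as integer codes compared by disagreement
  is_num <- vapply(table, is.numeric, logical(1))
  Z <- matrix(NA_real_, nrow(table), p)
  for (j in seq_len(p)) {
    v <- table[[j]]
    if (is_num[j]) {
      m <- mean(v[fitted_on], na.rm = TRUE)
      s <- stats::sd(v[fitted_on], na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      Z[, j] <- (v - m) / s
    } else {
      Z[, j] <- as.integer(factor(v))
    }
  }
  out <- table
  for (j in seq_len(p)) {
    miss <- which(is.na(table[[j]]))
    if (!length(miss)) next
    donors <- intersect(fitted_on, which(!is.na(table[[j]])))
    if (length(donors) < k)
      stop(sprintf("fewer than k = %d donors for feature '%s'", k,
                   names(table)[j]))
    for (i in miss) {
      d2 <- knn_dist2(Z, i, donors, exclude = j, is_num = is_num)
      ord <- donors[order(d2, donors)][seq_len(k)]
      vals <- table[[j]][ord]
      if (is_num[j]) {
        out[[j]][i] <- mean(vals)
      } else {
        # mean of one-hot donors = category frequencies; take the argmax,
        # first-seen order breaking ties
        tab <- table(factor(vals, levels = unique(vals)))
        out[[j]][i] <- names(tab)[which.max(tab)]
      }
    }
  }
  out
}

knn_dist2 <- function(Z, i, donors, exclude, is_num) {
  cols <- setdiff(seq_len(ncol(Z)), exclude)
  zi <- Z[i, cols]
  zd <- Z[donors, cols, drop = FALSE]
  diff <- sweep(zd, 2, zi)
  if (any(!is_num[cols])) {
    cc <- which(!is_num[cols])
    diff[, cc] <- (abs(diff[, cc]) > 0) * 1
  }
  d2 <- diff^2
  co <- !is.na(d2)
  nco <- rowSums(co)
  d2[!co] <- 0
  res <- rowSums(d2) / pmax(nco, 1)      # mean over co-observed, rescaled
  res[nco == 0] <- Inf
  res
}

#' Chained-equations imputation
#'
#' Deterministic chained-equations sweep: initialize holes with
#' median/mode, then cycle the incomplete columns in fixed order, regressing
#' each on all other columns (linear least squares for numeric targets;
#' per-category linear scores with argmax for categorical targets) and
#' overwriting the imputed cells with the predictions; repeat
#' \code{iters} times. Predictions are deterministic given the seed (the
#' seed only matters if a future stochastic variant draws residuals; the
#' default draws none). A singular regression falls back to the median/mode
#' for that column with a warning.
#'
#' @inheritParams impute_median
#' @param iters Number of sweeps (>= 1).
#' @param seed Integer seed.
#' @return Completed data.frame.
#' @export
impute_mice <- function(table, iters = 10, seed = 1,
                        fitted_on = seq_len(nrow(table))) {
  stopifnot(iters >= 1, ncol(table) >= 2)
  set.seed(seed)
  miss_idx <- lapply(table, function(v) which(is.na(v)))
  out <- impute_median(table, fitted_on = fitted_on)
  attr(out, "impute_stats") <- NULL
  incomplete <- names(table)[vapply(miss_idx, length, integer(1)) > 0]
  if (!length(incomplete)) return(out)
  for (it in seq_len(iters)) {
    for (nm in incomplete) {
      holes <- miss_idx[[nm]]
      rhs <- out[setdiff(names(out), nm)]
      X <- stats::model.matrix(~ ., data = rhs)
      y <- out[[nm]]
      train <- setdiff(fitted_on, holes)
      pred <- tryCatch({
        if (is.numeric(y)) {
          fit <- stats::lm.fit(X[train, , drop = FALSE], y[train])
          b <- fit$coefficients
          b[is.na(b)] <- 0
          as.numeric(X[holes, , drop = FALSE] %*% b)
        } else {
          lv <- unique(y[train])
          scores <- sapply(lv, function(l) {
            fit <- stats::lm.fit(X[train, , drop = FALSE],
                                 as.numeric(y[train] == l))
            b <- fit$coefficients
            b[is.na(b)] <- 0
            as.numeric(X[holes, , drop = FALSE] %*% b)
          })
          if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
          lv[max.col(scores, ties.method = "first")]
        }
      }, error = function(e) {
        warning("singular regression for '", nm,
                "'; falling back to median/mode")
        NULL
      })
      if (!is.null(pred) && all(is.finite(as.numeric(
        if (is.numeric(y)) pred else 0)))) {
        out[[nm]][holes] <- pred
      }
    }
  }
  out
}

#' Fit / apply the one-hot + z-score transform
#'
#' Learns category lists, means and standard deviations on a (complete)
#' fitting table and produces the model-ready design matrix: each
#' categorical feature with L levels becomes L indicator columns
#' (\code{feature=level}); numeric features are z-scored with the fitting
#' means/sds (a constant column gets sd 1, so it maps to 0). The fitted
#' transform is reusable on new data; a category unseen at fit time yields
#' all-zero indicators with a warning.
#'
#' @param table Complete (imputed) data.frame of features.
#' @param scale Z-score numeric columns (default TRUE).
#' @return A list of class \code{design_transform} with the fitted
#'   parameters; apply it with [apply_transform()].
#' @export
fit_transform <- function(table, scale = TRUE) {
  stopifnot(!anyNA(table))
  params <- lapply(names(table), function(nm) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      list(type = "numeric", mean = if (scale) mean(v) else 0,
           sd = if (scale && is.finite(s) && s > 0) s else 1)
    } else {
      list(type = "categorical", levels = sort(unique(as.character(v))))
    }
  })
  names(params) <- names(table)
  structure(list(params = params, scale = scale),
            class = "design_transform")
}

#' @rdname fit_transform
#' @param transform A fitted \code{design_transform}.
#' @param new_table Data.frame with the same feature columns.
#' @export
apply_transform <- function(transform, new_table) {
  stopifnot(inherits(transform, "design_transform"),
            all(names(transform$params) %in% names(new_table)))
  cols <- list()
  for (nm in names(transform$params)) {
    p <- transform$params[[nm]]
    v <- new_table[[nm]]
    if (p$type == "numeric") {
      cols[[nm]] <- (as.numeric(v) - p$mean) / p$sd
    } else {
      v <- as.character(v)
      unseen <- setdiff(unique(v), p$levels)
      if (length(unseen))
        warning("unseen categories in '", nm, "': ",
                paste(unseen, collapse = ", "), " (all-zero indicators)")
      for (l in p$levels) cols[[paste0(nm, "=", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Impute then encode in one step
#'
#' Convenience wrapper used by the harness: fits the chosen imputer and the
#' one-hot/z-score transform on the training rows, applies both to any
#' table.
#'
#' @param table Raw feature data.frame.
#' @param method One of \code{"median"}, \code{"knn"}, \code{"mice"}.
#' @param k Neighbours for KNN.
#' @param mice_iters Sweeps for chained equations.
#' @param seed Seed for chained equations.
#' @param fitted_on Training row indices.
#' @return List with \code{x} (design matrix over all rows) and
#'   \code{transform}.
#' @export
preprocess_features <- function(table, method = c("median", "knn", "mice"),
                                k = 2, mice_iters = 10, seed = 1,
                                fitted_on = seq_len(nrow(table))) {
  method <- match.arg(method)
  completed <- switch(method,
    median = impute_median(table, fitted_on = fitted_on),
    knn = impute_knn(table, k = k, fitted_on = fitted_on),
    mice = impute_mice(table, iters = mice_iters, seed = seed,
                       fitted_on = fitted_on))
  transform <- fit_transform(as.data.frame(completed[fitted_on, ,
                                                     drop = FALSE]))
  list(x = apply_transform(transform, completed), transform = transform,
       completed = completed)
}
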