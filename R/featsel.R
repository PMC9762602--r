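#' Univariate Cox screening by Wald test
#'
#' Fits a one-covariate Cox proportional-hazards model per design-matrix
#' column (Breslow ties) and keeps the columns whose Wald p-value falls
#' below \code{alpha}. Columns whose fit does not converge (constant
#' columns, separation) are dropped and listed in the result's log.
#'
#' @param x Design matrix.
#' @param time,event Outcome (>= 2 events).
#' @param alpha Wald p-value threshold (default 0.001).
#' @return Object of class \code{selection_result}: \code{kept} (ordered
#'   column names), \code{stat} (named Wald p-values of all scored
#'   columns), \code{method}, \code{log}.
#' @export
univariate_cox_select <- function(x, time, event, alpha = 0.001) {
  x <- as.matrix(x)
  stopifnot(sum(event == 1) >= 2, alpha > 0, alpha <= 1)
  y <- survival::Surv(time, event)
  pvals <- rep(NA_real_, ncol(x))
  names(pvals) <- colnames(x)
  log <- character(0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (stats::sd(v) == 0) {
      log <- c(log, sprintf("column '%s': constant, dropped",
                            colnames(x)[j]))
      next
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ v, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)) ||
        !isTRUE(is.finite(sqrt(stats::vcov(fit)[1, 1])))) {
      log <- c(log, sprintf("column '%s': non-convergence, dropped",
                            colnames(x)[j]))
      next
    }
    z <- stats::coef(fit)[1] / sqrt(stats::vcov(fit)[1, 1])
    pvals[j] <- 2 * stats::pnorm(-abs(z))
  }
  kept <- names(pvals)[!is.na(pvals) & pvals < alpha]
  structure(list(kept = kept, stat = pvals, method = "univariate_cox",
                 log = log), class = "selection_result")
}

#' Recursive feature elimination with a Cox model
#'
#' Repeatedly fits a multivariable Cox model (Breslow ties) on the current
#' column set and removes the column with the smallest Wald |z| =
#' |coef|/se, until \code{n_keep} remain. A singular fit is stabilized by
#' refitting with a small ridge penalty (logged); a coefficient that is
#' still inestimable gets |z| = 0 and is eliminated first.
#'
#' @inheritParams univariate_cox_select
#' @param n_keep Number of columns to retain (default 10).
#' @return \code{selection_result} with \code{stat} = elimination rank
#'   (1 = eliminated first) for removed columns, NA for kept ones.
#' @export
rfe_cox_select <- function(x, time, event, n_keep = 10) {
  x <- as.matrix(x)
  stopifnot(n_keep >= 1, n_keep <= ncol(x), sum(event == 1) >= 2)
  y <- survival::Surv(time, event)
  current <- colnames(x)
  rank <- rep(NA_real_, ncol(x))
  names(rank) <- colnames(x)
  log <- character(0)
  step <- 0
  while (length(current) > n_keep) {
    xs <- x[, current, drop = FALSE]
    z <- tryCatch({
      fit <- suppressWarnings(survival::coxph(y ~ xs, ties = "breslow"))
      cf <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
      zz <- abs(cf) / se
      zz[!is.finite(zz)] <- 0
      zz
    }, error = function(e) NULL)
    if (is.null(z)) {
      log <- c(log, sprintf("step %d: singular fit, ridge-stabilized",
                            step + 1))
      fit <- suppressWarnings(survival::coxph(
        y ~ survival::ridge(xs, theta = 1), ties = "breslow"))
      cf <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
      z <- abs(cf) / se
      z[!is.finite(z)] <- 0
    }
    worst <- which.min(z)          # ties broken by column order
    step <- step + 1
    rank[current[worst]] <- step
    current <- current[-worst]
  }
  structure(list(kept = current, stat = rank, method = "rfe_cox",
                 log = log), class = "selection_result")
}

#' mRMR selection with a concordance relevance score
#'
#' Greedy minimum-redundancy maximum-relevance selection adapted to
#' censored outcomes: the relevance of column f is |C(f) - 0.5| where C(f)
#' is the concordance index of ranking subjects by f alone against the
#' censored outcome (so protective and deleterious columns score
#' symmetrically); the redundancy of f against the selected set S is the
#' mean absolute Pearson correlation with S. The first pick maximizes
#' relevance; each later pick maximizes relevance(f) - redundancy(f, S)
#' (the difference form). Ties break by column order.
#'
#' @inheritParams rfe_cox_select
#' @return \code{selection_result} with \code{stat} = the greedy score at
#'   selection time for kept columns.
#' @export
mrmr_cindex_select <- function(x, time, event, n_keep = 10) {
  x <- as.matrix(x)
  stopifnot(n_keep >= 1, n_keep <= ncol(x))
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(j) {
    if (stats::sd(x[, j]) == 0) return(0)
    abs(c_index(x[, j], time, event) - 0.5)
  }, numeric(1))
  names(relevance) <- colnames(x)
  selected <- integer(0)
  score <- rep(NA_real_, p)
  names(score) <- colnames(x)
  for (pick in seq_len(n_keep)) {
    cand <- setdiff(seq_len(p), selected)
    val <- vapply(cand, function(j) {
      if (!length(selected)) return(relevance[j])
      red <- mean(vapply(selected, function(s) {
        if (stats::sd(x[, j]) == 0 || stats::sd(x[, s]) == 0) return(0)
        abs(stats::cor(x[, j], x[, s]))
      }, numeric(1)))
      relevance[j] - red
    }, numeric(1))
    best <- cand[which.max(val)]
    score[best] <- max(val)
    selected <- c(selected, best)
  }
  structure(list(kept = colnames(x)[selected], stat = score,
                 relevance = relevance, method = "mrmr_cindex",
                 log = character(0)), class = "selection_result")
}

#' Elastic-net Cox feature selection
#'
#' Fits an elastic-net-penalized Cox model over a regularization path for
#' each candidate lasso/ridge mixing ratio, scores every (ratio, lambda)
#' point by the mean internal cross-validated C-index, and keeps the
#' columns with nonzero coefficients at the best point. Coefficients are
#' reported signed, sorted by decreasing magnitude.
#'
#' @inheritParams univariate_cox_select
#' @param l1_ratio_grid Candidate elastic-net mixing ratios (glmnet alpha;
#'   1 = lasso).
#' @param cv_folds Internal folds for the C-index criterion.
#' @param seed Seed controlling the internal fold assignment.
#' @param nlambda Path length per ratio.
#' @return \code{selection_result} with \code{stat} = the nonzero signed
#'   coefficients (named, sorted by |coefficient| descending), plus
#'   \code{l1_ratio} and \code{lambda} chosen.
#' @export
coxnet_select <- function(x, time, event,
                          l1_ratio_grid = c(0.25, 0.5, 0.75, 1),
                          cv_folds = 5, seed = 1, nlambda = 50) {
  x <- as.matrix(x)
  stopifnot(sum(event == 1) >= cv_folds)
  y <- survival::Surv(time, event)
  set.seed(seed)
  foldid <- stratified_splits(time, event, k = cv_folds, seed = seed)
  best <- NULL
  for (a in l1_ratio_grid) {
    cv <- tryCatch(
      glmnet::cv.glmnet(x, y, family = "cox", type.measure = "C",
                        alpha = a, foldid = foldid, nlambda = nlambda),
      error = function(e) NULL)
    if (is.null(cv)) next
    i <- which.max(cv$cvm)
    if (is.null(best) || cv$cvm[i] > best$cvm) {
      best <- list(cvm = cv$cvm[i], lambda = cv$lambda[i], alpha = a,
                   fit = cv$glmnet.fit)
    }
  }
  if (is.null(best)) stop("all elastic-net paths failed")
  beta <- as.numeric(stats::coef(best$fit, s = best$lambda))
  names(beta) <- rownames(stats::coef(best$fit, s = best$lambda))
  nz <- beta[beta != 0]
  nz <- nz[order(-abs(nz))]
  if (!length(nz)) warning("elastic-net optimum selected zero features")
  structure(list(kept = names(nz), stat = nz, method = "coxnet",
                 l1_ratio = best$alpha, lambda = best$lambda,
                 cv_c_index = best$cvm, log = character(0)),
            class = "selection_result")
}

#' Passthrough (no selection)
#'
#' @inheritParams univariate_cox_select
#' @return \code{selection_result} keeping every column.
#' @export
select_none <- function(x, time, event) {
  structure(list(kept = colnames(as.matrix(x)), stat = NULL,
                 method = "none", log = character(0)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features kept\n", x$method,
              length(x$kept)))
  if (length(x$kept)) cat(" ", paste(utils::head(x$kept, 12),
                                     collapse = ", "),
                          if (length(x$kept) > 12) "..." else "", "\n")
  invisible(x)
}

#' Export a selection result as the standard feature table
#'
#' One row per kept feature: name, statistic, coefficient (elastic net
#' only) and the actionable/intrinsic flag looked up from the schema by
#' the source-feature prefix of the column name.
#'
#' @param sel A \code{selection_result}.
#' @param schema Feature metadata, or NULL to skip the flag.
#' @param path Optional CSV output path.
#' @return data.frame.
#' @export
selection_table <- function(sel, schema = NULL, path = NULL) {
  kept <- sel$kept
  stat <- if (!is.null(sel$stat)) sel$stat[kept] else rep(NA_real_,
                                                          length(kept))
  tab <- data.frame(feature = kept, statistic = as.numeric(stat),
                    coefficient = if (sel$method == "coxnet")
                      as.numeric(stat) else NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    src <- sub("=.*$", "", kept)
    idx <- match(src, schema$name)
    tab$type <- ifelse(is.na(idx), NA,
                       ifelse(schema$actionable[idx], "Actionable",
                              "Intrinsic"))
  }
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
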