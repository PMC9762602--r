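#' Multi-task logistic regression (MTLR) survival model
#'
#' MTLR discretizes time on a grid tau_1 < ... < tau_m and encodes each
#' subject's outcome as the monotone binary sequence y with y_j = 1 iff the
#' event occurred by tau_j. A sequence that switches after position k (event
#' in (tau_k, tau_{k+1}]) scores f(y, x) = sum_{j > k} (theta_j . x + b_j),
#' and the model places probability proportional to exp(f) on each of the
#' m + 1 legal monotone sequences. Uncensored subjects contribute the
#' probability of the sequence switching in the interval containing their
#' event time; censored subjects marginalize over every sequence with event
#' after the censoring time (the censoring time is assigned to the nearest
#' lower grid index). The fit minimizes the summed negative log-likelihood
#' plus an L2 penalty (C/2)||Theta||^2 and a smoothness penalty
#' lambda_s * sum_j ||theta_{j+1} - theta_j||^2 coupling adjacent time
#' points, by L-BFGS from zero initialization (deterministic).
#'
#' @param x Numeric design matrix (n x d); d = 0 (bias-only) is allowed and
#'   recovers a discrete Kaplan-Meier-type fit.
#' @param time Observed times in months.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param C L2 strength on the weights (biases unpenalized).
#' @param smoothness Strength of the adjacent-time smoothness penalty.
#' @param n_intervals Grid size m; default \code{ceiling(sqrt(#events))}.
#' @param grid Explicit strictly increasing grid (overrides
#'   \code{n_intervals}).
#' @param maxit,pgtol L-BFGS iteration cap and projected-gradient
#'   tolerance.
#' @param trace Record the objective after every 10 iterations
#'   (\code{$loss_trace}).
#' @return Object of class \code{mtlr_fit}: \code{tau} (grid),
#'   \code{theta} (m x d), \code{bias} (length m), hyperparameters, fitted
#'   column names, convergence info.
#' @export
fit_mtlr <- function(x, time, event, C = 1, smoothness = 0,
                     n_intervals = NULL, grid = NULL, maxit = 500,
                     pgtol = 1e-5, trace = FALSE) {
  x <- as.matrix(x)
  n <- length(time)
  stopifnot(nrow(x) == n || ncol(x) == 0, length(event) == n,
            sum(event == 1) >= 2)
  d <- ncol(x)
  if (is.null(grid)) {
    ev_times <- time[event == 1]
    m <- if (is.null(n_intervals)) ceiling(sqrt(length(ev_times)))
         else n_intervals
    m <- max(m, 2L)
    qs <- stats::quantile(ev_times, probs = seq_len(m) / (m + 1),
                          names = FALSE, type = 7)
    grid <- unique(qs)
    if (length(grid) < 2) grid <- unique(c(grid, grid + 1))
  }
  stopifnot(all(diff(grid) > 0), length(grid) >= 2)
  tau <- as.numeric(grid)
  m <- length(tau)

  ## outcome encoding: uncensored -> the single interval index (0..m);
  ## censored -> tail from the nearest lower grid index
  j0 <- vapply(seq_len(n), function(i) {
    if (event[i] == 1) sum(tau < time[i]) else sum(tau <= time[i])
  }, numeric(1))

  nll_grad <- make_mtlr_objective(x, j0, event, tau, C, smoothness)
  npar <- m + m * d
  par0 <- numeric(npar)

  loss_trace <- NULL
  if (trace) {
    par <- par0
    val_prev <- Inf
    repeat {
      op <- stats::optim(par, nll_grad$fn, nll_grad$gr, method = "L-BFGS-B",
                         control = list(maxit = 10, pgtol = pgtol))
      loss_trace <- c(loss_trace, op$value)
      par <- op$par
      if (op$convergence == 0 || length(loss_trace) >= ceiling(maxit / 10) ||
          val_prev - op$value < 1e-10) break
      val_prev <- op$value
    }
    opt <- op
    opt$par <- par
  } else {
    opt <- stats::optim(par0, nll_grad$fn, nll_grad$gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, pgtol = pgtol))
  }
  if (!is.finite(opt$value))
    stop("non-finite MTLR loss at optimum")
  bias <- opt$par[seq_len(m)]
  theta <- if (d > 0) matrix(opt$par[-seq_len(m)], nrow = m, ncol = d)
           else matrix(0, m, 0)
  structure(list(tau = tau, theta = theta, bias = bias, C = C,
                 smoothness = smoothness, columns = colnames(x),
                 value = opt$value, convergence = opt$convergence,
                 loss_trace = loss_trace),
            class = "mtlr_fit")
}

# builds closures computing the penalized negative log-likelihood and its
# gradient; parameters packed as c(bias, vec(theta))
make_mtlr_objective <- function(x, j0, event, tau, C, smoothness) {
  n <- length(j0)
  m <- length(tau)
  d <- ncol(x)
  Tge <- lower.tri(matrix(0, m, m), diag = TRUE) * 1   # [j,k] = 1 iff j >= k
  unpack <- function(par) {
    list(b = par[seq_len(m)],
         th = if (d > 0) matrix(par[-seq_len(m)], m, d) else matrix(0, m, 0))
  }
  core <- function(par) {
    p <- unpack(par)
    g <- matrix(rep(p$b, each = n), n, m)           # n x m scores
    if (d > 0) g <- g + x %*% t(p$th)
    ## scores of the m+1 sequences: score(k) = sum_{j>k} g_j, k = 0..m
    sc <- cbind(g %*% Tge, 0)
    mx <- do.call(pmax, as.data.frame(sc))
    esc <- exp(sc - mx)
    Z <- rowSums(esc)
    P <- esc / Z                                     # n x (m+1) posteriors
    logZ <- log(Z) + mx
    ## log-likelihood per subject
    ll <- numeric(n)
    unc <- event == 1
    ll[unc] <- sc[cbind(which(unc), j0[unc] + 1)] - logZ[unc]
    if (any(!unc)) {
      idx <- which(!unc)
      tail_p <- vapply(idx, function(i) {
        sum(P[i, (j0[i] + 1):(m + 1)])
      }, numeric(1))
      ll[idx] <- log(pmax(tail_p, 1e-300))
    }
    list(P = P, sc = sc, ll = ll, g = g)
  }
  fn <- function(par) {
    p <- unpack(par)
    cr <- core(par)
    pen <- (C / 2) * sum(p$th^2)
    if (smoothness > 0 && m >= 2 && d > 0)
      pen <- pen + smoothness * sum(diff(p$th)^2)
    -sum(cr$ll) + pen
  }
  gr <- function(par) {
    p <- unpack(par)
    cr <- core(par)
    P <- cr$P
    ## F_full[i, l] = P(sequence index < l) for l = 1..m
    cumP <- P %*% (upper.tri(matrix(0, m + 1, m + 1), diag = TRUE) * 1)
    F_full <- cumP[, seq_len(m), drop = FALSE]
    ## F_T[i, l] = conditional P(index < l | allowed set)
    F_T <- matrix(0, n, m)
    unc <- event == 1
    if (any(unc)) {
      iu <- which(unc)
      # allowed set = {j0}; indicator j0 < l
      F_T[iu, ] <- outer(j0[iu], seq_len(m), FUN = "<") * 1
    }
    if (any(!unc)) {
      ic <- which(!unc)
      k0 <- j0[ic]
      base <- ifelse(k0 >= 1, cumP[cbind(ic, pmax(k0, 1))], 0)
      tailmass <- pmax(1 - base, 1e-300)
      num <- pmax(cumP[ic, seq_len(m), drop = FALSE] - base, 0)
      num[outer(k0, seq_len(m), FUN = ">=")] <- 0  # l <= k0 contributes 0
      F_T[ic, ] <- num / tailmass
    }
    D <- F_full - F_T                                # d(-ll)/dg, n x m
    gb <- colSums(D)
    if (d > 0) {
      gth <- t(D) %*% x + C * p$th
      if (smoothness > 0 && m >= 2) {
        df <- diff(p$th)
        sm <- matrix(0, m, d)
        sm[-m, ] <- sm[-m, , drop = FALSE] - 2 * df
        sm[-1, ] <- sm[-1, , drop = FALSE] + 2 * df
        gth <- gth + smoothness * sm
      }
      c(gb, as.numeric(gth))
    } else gb
  }
  list(fn = fn, gr = gr)
}

# survival values S(tau_k | x) for each row of x, as an n x m matrix
mtlr_survival <- function(fit, x) {
  x <- as.matrix(x)
  m <- length(fit$tau)
  n <- nrow(x)
  d <- ncol(fit$theta)
  if (d > 0 && ncol(x) != d)
    stop(sprintf("design matrix has %d columns; model expects %d",
                 ncol(x), d))
  g <- matrix(rep(fit$bias, each = n), n, m)
  if (d > 0) g <- g + x %*% t(fit$theta)
  sc <- cbind(g %*% (lower.tri(matrix(0, m, m), diag = TRUE) * 1), 0)
  mx <- do.call(pmax, as.data.frame(sc))
  esc <- exp(sc - mx)
  P <- esc / rowSums(esc)
  ## S(tau_k) = P(sequence index >= k) = sum_{j >= k} P_j
  revcum <- P %*% (lower.tri(matrix(0, m + 1, m + 1), diag = TRUE) * 1)
  revcum[, 2:(m + 1), drop = FALSE]
}

#' Predict individual survival distributions from an MTLR fit
#'
#' @param fit An \code{mtlr_fit}.
#' @param x Design matrix of new subjects (columns as at fit time).
#' @param tail_rule Tail extrapolation rule for the returned curves.
#' @return List of [isd_curve()] objects, one per row.
#' @export
mtlr_predict <- function(fit, x, tail_rule = "linear_last_segment") {
  stopifnot(inherits(fit, "mtlr_fit"))
  x <- as.matrix(x)
  S <- mtlr_survival(fit, x)
  lapply(seq_len(nrow(S)), function(i)
    isd_curve(fit$tau, pmin(cummin(S[i, ]), 1), tail_rule = tail_rule))
}

#' Soft-L1-Hinge finetuning of a fitted MTLR model
#'
#' After likelihood pre-training, takes gradient steps on a differentiable
#' surrogate of the L1-Hinge loss. Two surrogate predicted times are
#' available, both differentiable in the parameters:
#' \describe{
#'   \item{\code{"soft_median"} (default)}{a smoothed median,
#'     \eqn{\hat t(x) = \sum_k (\tau_{k+1}-\tau_k)\,
#'     \sigma\{(S(\tau_k|x) - 0.5)/h\}}, the relaxation of
#'     \eqn{\int 1[S(t|x) > 0.5]\,dt}; as the temperature \eqn{h \to 0}
#'     this is exactly the median event time the L1-Hinge loss is
#'     evaluated at.}
#'   \item{\code{"expected_time"}}{the expected survival time
#'     \eqn{\hat t(x) = \sum_k S(\tau_k|x)(\tau_{k+1}-\tau_k)}. For
#'     right-skewed distributions this exceeds the median, so minimizing
#'     it can move the median-based L1-Hinge loss the wrong way; it is
#'     kept for comparison.}
#' }
#' Both use \eqn{\tau_0 = 0} and one trailing interval equal to the last
#' grid gap. The loss is the mean over uncensored subjects of a smoothed
#' \eqn{|\hat t - t|} plus the mean over censored subjects of
#' \eqn{\mathrm{softplus}(c - \hat t)}. Each epoch backtracks the step
#' until the surrogate does not increase; if the loss ever exceeds ten
#' times its initial value the finetuning aborts and the pre-trained
#' parameters are returned with a warning. \code{epochs = 0} is the
#' identity, and the monotone non-increasing shape of the predicted
#' curves is preserved structurally by the parameterization.
#'
#' @param fit A pre-trained \code{mtlr_fit}.
#' @param x,time,event Training design matrix and outcome.
#' @param epochs Number of gradient steps (>= 0).
#' @param step Initial step size.
#' @param surrogate \code{"soft_median"} or \code{"expected_time"}.
#' @param temperature Smoothing temperature h of the soft median, on the
#'   probability scale.
#' @return An updated \code{mtlr_fit} (same grid).
#' @export
finetune_soft_l1 <- function(fit, x, time, event, epochs = 20,
                             step = 1e-3,
                             surrogate = c("soft_median", "expected_time"),
                             temperature = 0.05) {
  surrogate <- match.arg(surrogate)
  stopifnot(inherits(fit, "mtlr_fit"), epochs >= 0)
  if (epochs == 0) return(fit)
  x <- as.matrix(x)
  n <- length(time)
  m <- length(fit$tau)
  d <- ncol(fit$theta)
  w <- c(fit$tau[1], diff(fit$tau),
         if (m >= 2) fit$tau[m] - fit$tau[m - 1] else fit$tau[1])
  eps <- 1e-4
  softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

  pack <- function(f) c(f$bias, as.numeric(f$theta))
  loss_grad <- function(par) {
    b <- par[seq_len(m)]
    th <- if (d > 0) matrix(par[-seq_len(m)], m, d) else matrix(0, m, 0)
    g <- matrix(rep(b, each = n), n, m)
    if (d > 0) g <- g + x %*% t(th)
    sc <- cbind(g %*% (lower.tri(matrix(0, m, m), diag = TRUE) * 1), 0)
    mx <- do.call(pmax, as.data.frame(sc))
    esc <- exp(sc - mx)
    P <- esc / rowSums(esc)                       # n x (m+1)
    cumP <- P %*% (upper.tri(matrix(0, m + 1, m + 1), diag = TRUE) * 1)
    Fm <- cumP[, seq_len(m), drop = FALSE]        # F_l = P(index < l)
    S <- 1 - Fm                                   # S(tau_k), k = 1..m
    wk <- w[2:(m + 1)]
    if (surrogate == "soft_median") {
      ## trapezoid rule on the grid nodes (left-endpoint rules bias the
      ## soft median upward by half a gap), plus one extension interval
      sig <- stats::plogis((S - 0.5) / temperature)
      v <- c((w[seq_len(m - 1)] + w[seq_len(m - 1) + 1]) / 2,
             w[m] / 2 + w[m + 1])
      w0 <- (w[1] / 2) * stats::plogis(0.5 / temperature)  # S(0) = 1 node
      that <- w0 + as.numeric(sig %*% v)
      dthat_dS <- sweep(sig * (1 - sig) / temperature, 2, v, `*`)
    } else {
      that <- w[1] + as.numeric(S %*% wk)
      dthat_dS <- matrix(rep(wk, each = n), n, m)
    }
    du <- that - time
    lu <- sqrt(du^2 + eps)
    lc <- softplus(time - that)
    unc <- event == 1
    loss <- (if (any(unc)) mean(lu[unc]) else 0) +
      (if (any(!unc)) mean(lc[!unc]) else 0)
    ## psi_i = dloss/dthat_i
    psi <- numeric(n)
    if (any(unc)) psi[unc] <- (du[unc] / lu[unc]) / sum(unc)
    if (any(!unc)) psi[!unc] <- -stats::plogis(time[!unc] - that[!unc]) /
      sum(!unc)
    ## dthat_i/dg_il = sum_k dthat/dS_k * [ (F_l - F_k)_+ - (1 - F_k) F_l ]
    G <- matrix(0, n, m)
    for (i in seq_len(n)) {
      Fi <- Fm[i, ]
      A <- outer(Fi, Fi, function(fl, fk) pmax(fl - fk, 0)) # [l, k]
      B <- outer(Fi, 1 - Fi)                                # F_l (1 - F_k)
      G[i, ] <- as.numeric((A - B) %*% dthat_dS[i, ])
    }
    dg <- psi * G
    gb <- colSums(dg)
    gpar <- if (d > 0) c(gb, as.numeric(t(dg) %*% x)) else gb
    list(loss = loss, grad = gpar)
  }

  par <- pack(fit)
  lg <- loss_grad(par)
  init_loss <- lg$loss
  cur_step <- step
  for (ep in seq_len(epochs)) {
    trial <- par - cur_step * lg$grad
    lt <- loss_grad(trial)
    tries <- 0
    while (lt$loss > lg$loss && tries < 20) {
      cur_step <- cur_step / 2
      trial <- par - cur_step * lg$grad
      lt <- loss_grad(trial)
      tries <- tries + 1
    }
    if (lt$loss > 10 * init_loss) {
      warning("soft-L1-Hinge finetuning diverged; returning ",
              "pre-trained parameters")
      return(fit)
    }
    if (lt$loss > lg$loss) break                  # no descent direction left
    par <- trial
    lg <- lt
    cur_step <- min(cur_step * 2, step)
  }
  fit$bias <- par[seq_len(m)]
  if (d > 0) fit$theta <- matrix(par[-seq_len(m)], m, d)
  fit
}
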