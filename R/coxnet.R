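# Observation-weighted elastic-net Cox regression by pathwise coordinate
# descent.  Breslow tie handling; counting-process (start, stop] intervals
# with left truncation; outer IRLS on the partial likelihood with an inner
# penalized weighted-least-squares coordinate descent (compiled).

# Precomputed time-ordering structures for the weighted Breslow partial
# likelihood on (start, stop] intervals.  Everything here depends only on
# the survival coordinates and weights, never on the linear predictor, so
# it is built once per fit and reused across IRLS iterations.
cox_prep <- function(start, stop, event, w) {
  ev <- event == 1
  te <- sort(unique(stop[ev]))
  if (length(te) == 0L) stop("no events")
  Dt <- numeric(length(te))
  agg <- rowsum(w[ev], match(stop[ev], te))
  Dt[as.integer(rownames(agg))] <- agg
  o_start <- order(start); o_stop <- order(stop)
  list(start = start, stop = stop, event = event, w = w, ev = ev, te = te,
       Dt = Dt, o_start = o_start, o_stop = o_stop,
       # S0(t) = sum_{start_j < t} r_j - sum_{stop_j < t} r_j
       n_start_lt = findInterval(te, start[o_start], left.open = TRUE),
       n_stop_lt = findInterval(te, stop[o_stop], left.open = TRUE),
       # event times in (start_i, stop_i]: cumulative-index range (k1, k2]
       k2 = findInterval(stop, te), k1 = findInterval(start, te),
       w_ev = w[ev])
}

# Risk-set quantities at a linear predictor eta.  For each observation i:
#   A_i = sum over event times t in (start_i, stop_i] of D_t / S0(t)
#   B_i = same with D_t / S0(t)^2
# with D_t the weighted death count at t and S0(t) the weighted at-risk sum
# of exp(eta).  Returns the weighted Breslow log partial likelihood, and
# (unless loglik_only) the gradient g and diagonal Hessian h of the
# negative log partial likelihood with respect to eta.
cox_quant <- function(prep, eta, loglik_only = FALSE) {
  r <- prep$w * exp(eta)
  cs_start <- c(0, cumsum(r[prep$o_start]))
  cs_stop <- c(0, cumsum(r[prep$o_stop]))
  S0 <- cs_start[prep$n_start_lt + 1L] - cs_stop[prep$n_stop_lt + 1L]
  if (any(S0 <= 0)) stop("degenerate risk set (empty at an event time)")
  loglik <- sum(prep$w_ev * eta[prep$ev]) - sum(prep$Dt * log(S0))
  if (loglik_only) return(list(loglik = loglik))
  c1 <- c(0, cumsum(prep$Dt / S0))
  c2 <- c(0, cumsum(prep$Dt / S0^2))
  A <- c1[prep$k2 + 1L] - c1[prep$k1 + 1L]
  B <- c2[prep$k2 + 1L] - c2[prep$k1 + 1L]
  g <- -(prep$w * prep$event - r * A)   # d(-logPL)/d eta
  h <- r * A - r^2 * B                  # diag of d2(-logPL)/d eta2
  list(loglik = loglik, g = g, h = h)
}

# Back-compatible one-shot interface (used by tests/oracles).
cox_risk_quantities <- function(start, stop, event, w, eta, ...) {
  cox_quant(cox_prep(start, stop, event, w), eta, ...)
}

# Gradient of the (weight-normalized) negative log partial likelihood with
# respect to the coefficients, on the standardized-feature scale.
cox_score <- function(xs, prep, beta) {
  q <- cox_quant(prep, drop(xs %*% beta))
  drop(crossprod(xs, q$g))
}

#' Observation-weighted elastic-net Cox regression path
#'
#' Fits the penalized Cox model
#' \deqn{\min_\beta -\ell_w(\beta) + \lambda[\alpha\|\beta\|_1 +
#'   (1-\alpha)/2\,\|\beta\|_2^2]}
#' where \eqn{\ell_w} is the weight-normalized Breslow log partial
#' likelihood on counting-process intervals `(start, stop]` (left truncation
#' supported), over a decreasing lambda path computed warm-started from the
#' all-zero solution at `lambda_max` downward. Features are standardized
#' internally to weighted mean zero / unit variance; coefficients are
#' reported on the original feature scale. The solver is outer IRLS on the
#' partial likelihood with a compiled coordinate-descent inner loop, with
#' step halving to keep the penalized objective non-increasing.
#'
#' @param x numeric matrix, samples x features (column names = feature IDs).
#' @param start,stop,event counting-process survival coordinates; `start`
#'   may be omitted (`NULL`) for right-censored data without truncation.
#' @param weights nonnegative per-sample observation weights (default 1).
#' @param alpha elastic-net mixing in \[0, 1\] (1 = lasso, 0 = ridge;
#'   default 0.5).
#' @param lambda optional decreasing lambda sequence; computed automatically
#'   when `NULL`.
#' @param nlambda length of the automatic path (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`
#'   (default 1e-3).
#' @param thresh convergence tolerance on the maximum coefficient change
#'   (standardized scale) for both inner and outer loops (default 1e-7).
#' @param maxit maximum inner coordinate-descent iterations per subproblem.
#' @param maxit_outer maximum IRLS iterations per lambda.
#' @param devmax stop the path early once the fraction of null deviance
#'   explained exceeds this value (default 0.99), truncating the lambda
#'   sequence; guards against near-saturated, unidentifiable fits deep in
#'   the path.
#' @return An object of class `coxnet`: list with `beta` (features x
#'   nlambda, original scale), `beta_std` (standardized scale), `lambda`,
#'   `alpha`, `df`, `center`, `scale`, `obj` (penalized objective per
#'   lambda), `max_obj_increase` (largest observed objective increase across
#'   IRLS steps; ~0 certifies monotone descent) and `nulldev_loglik`.
#' @references Simon, N., Friedman, J., Hastie, T., Tibshirani, R. (2011).
#'   Regularization paths for Cox's proportional hazards model via
#'   coordinate descent. Journal of Statistical Software 39(5).
#' @export
coxnet <- function(x, start = NULL, stop, event, weights = NULL,
                   alpha = 0.5, lambda = NULL, nlambda = 100L,
                   lambda_min_ratio = 1e-3, thresh = 1e-7,
                   maxit = 1e5L, maxit_outer = 50L, devmax = 0.99) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(start)) start <- rep(-Inf, n)
  stopifnot(length(start) == n, length(stop) == n, length(event) == n)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (sum(event) < 2) stop("need at least 2 events")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("weights must not be all zero")
  if (any(!is.finite(x))) stop("features must be finite (impute first)")
  wn <- weights / sum(weights)

  # weighted standardization
  ctr <- drop(wn %*% x)
  xc <- sweep(x, 2L, ctr)
  scl <- sqrt(drop(wn %*% xc^2))
  ok <- scl > 0
  scl[!ok] <- 1
  xs <- sweep(xc, 2L, scl, "/")

  prep <- cox_prep(start, stop, event, wn)

  # lambda path from the null-model gradient
  score0 <- abs(cox_score(xs, prep, rep(0, p)))
  lambda_max <- max(score0[ok]) / max(alpha, 1e-3) * (1 + 1e-6)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    if (is.unsorted(rev(lambda), strictly = TRUE))
      stop("lambda path must be strictly decreasing")
  }
  nlam <- length(lambda)

  penalty <- function(b) sum(alpha * abs(b) + (1 - alpha) / 2 * b^2)

  beta_std <- matrix(0, p, nlam,
                     dimnames = list(colnames(x), format(seq_len(nlam))))
  obj <- numeric(nlam)
  max_obj_inc <- 0
  b <- rep(0, p)
  eta <- rep(0, n)
  q <- cox_quant(prep, eta)
  ll_null <- q$loglik
  f_b <- -q$loglik  # objective at b (penalty of zero vector is 0)
  for (l in seq_len(nlam)) {
    lam <- lambda[l]
    f_b <- f_b - lambda[max(l - 1L, 1L)] * penalty(b) + lam * penalty(b)
    it_outer <- 0L
    converged <- FALSE
    while (it_outer < maxit_outer) {
      it_outer <- it_outer + 1L
      h <- pmax(q$h, 1e-12 * max(q$h, 1e-300))
      z <- eta - q$g / h
      sol <- cd_enet_wls(xs, h, z, b, alpha, lam, thresh, as.integer(maxit))
      if (sol$iter >= maxit && sol$dmax >= thresh)
        stop(sprintf("coordinate descent exceeded maxit at lambda = %.6g",
                     lam))
      b_new <- sol$b
      b_new[!ok] <- 0
      eta_new <- drop(xs %*% b_new)
      q_new <- cox_quant(prep, eta_new)
      f_new <- -q_new$loglik + lam * penalty(b_new)
      # step-halve toward the previous iterate if the IRLS step overshoots,
      # keeping the penalized objective non-increasing
      step <- 1
      while (f_new > f_b + 1e-12 && step > 1e-4) {
        step <- step / 2
        b_new <- b + step * (sol$b - b)
        b_new[!ok] <- 0
        eta_new <- drop(xs %*% b_new)
        q_new <- cox_quant(prep, eta_new)
        f_new <- -q_new$loglik + lam * penalty(b_new)
      }
      if (f_new > f_b) max_obj_inc <- max(max_obj_inc, f_new - f_b)
      delta <- max(abs(b_new - b))
      b <- b_new; q <- q_new; f_b <- f_new; eta <- eta_new
      if (delta < thresh * 10) { converged <- TRUE; break }
    }
    if (!converged && delta > 1e-6) {
      # near-unidentifiable fits deep in the path (features ~ events):
      # truncate rather than return an unconverged solution
      if (l == 1L)
        stop(sprintf("coxnet did not converge at lambda = %.6g", lam))
      warning(sprintf("path truncated at lambda = %.6g (IRLS not converged)",
                      lam))
      lambda <- lambda[seq_len(l - 1L)]
      beta_std <- beta_std[, seq_len(l - 1L), drop = FALSE]
      obj <- obj[seq_len(l - 1L)]
      break
    }
    beta_std[, l] <- b
    obj[l] <- f_b
    dev_ratio <- 1 - q$loglik / ll_null
    if (dev_ratio > devmax && l < nlam) {  # near-saturated: truncate path
      lambda <- lambda[seq_len(l)]
      beta_std <- beta_std[, seq_len(l), drop = FALSE]
      obj <- obj[seq_len(l)]
      break
    }
  }

  beta_orig <- beta_std / scl
  structure(list(beta = beta_orig, beta_std = beta_std, lambda = lambda,
                 alpha = alpha, df = colSums(beta_std != 0),
                 center = ctr, scale = scl,
                 obj = obj, max_obj_increase = max_obj_inc,
                 nulldev_loglik = ll_null,
                 nobs = n, nevents = sum(event)),
            class = "coxnet")
}

#' @export
print.coxnet <- function(x, ...) {
  cat(sprintf("coxnet path: %d features, %d lambdas (alpha = %g), %d obs / %d events\n",
              nrow(x$beta), length(x$lambda), x$alpha, x$nobs, x$nevents))
  cat(sprintf("  df range %d-%d; lambda %.4g .. %.4g\n",
              min(x$df), max(x$df), max(x$lambda), min(x$lambda)))
  invisible(x)
}

#' @export
coef.coxnet <- function(object, lambda = NULL, ...) {
  if (is.null(lambda)) return(object$beta)
  l <- which.min(abs(object$lambda - lambda))
  object$beta[, l]
}

#' Karush-Kuhn-Tucker residuals along a coxnet path
#'
#' For each lambda, computes the stationarity residuals of the penalized
#' weighted partial likelihood on the standardized scale: for an active
#' coefficient, `score_j + lambda alpha sign(b_j) + lambda (1-alpha) b_j`
#' (should be ~0); for a zero coefficient, the amount by which `|score_j|`
#' exceeds `lambda alpha` (0 when the subgradient condition holds).
#'
#' @param fit a [coxnet()] object.
#' @param x,start,stop,event,weights the data the path was fit on.
#' @return Numeric vector: the maximum absolute KKT residual per lambda.
#' @export
coxnet_kkt <- function(fit, x, start = NULL, stop, event, weights = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(start)) start <- rep(-Inf, n)
  if (is.null(weights)) weights <- rep(1, n)
  wn <- weights / sum(weights)
  xs <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  prep <- cox_prep(start, stop, event, wn)
  vapply(seq_along(fit$lambda), function(l) {
    b <- fit$beta_std[, l]
    s <- cox_score(xs, prep, b)
    lam <- fit$lambda[l]
    viol_zero <- pmax(abs(s) - lam * fit$alpha, 0)[b == 0]
    viol_act <- abs(s + lam * fit$alpha * sign(b) +
                    lam * (1 - fit$alpha) * b)[b != 0]
    max(c(viol_zero, viol_act, 0))
  }, 0)
}

#' Cross-validated lambda selection for weighted elastic-net Cox
#'
#' K-fold cross-validation at the woman level with folds stratified by event
#' status (so every fold contains events). The criterion is the
#' cross-validated partial-likelihood deviance of Verweij and van
#' Houwelingen: for fold k,
#' `dev_k = -2 [ logPL(all data; beta_{-k}) - logPL(without fold k; beta_{-k}) ]`.
#' The chosen lambda minimizes the mean deviance across folds
#' (`lambda_min`); the largest lambda within one fold standard error is also
#' reported (`lambda_1se`).
#'
#' @inheritParams coxnet
#' @param nfolds number of folds (default 10); must not exceed the event
#'   count.
#' @param foldid optional integer fold assignment (overrides `seed`).
#' @param seed integer seed for the fold draw.
#' @param fold_thresh convergence tolerance for the fold fits (default
#'   1e-5). Fold coefficients only feed the cross-validated deviance, which
#'   is insensitive at this scale, so the folds can run looser than the
#'   final full-data path.
#' @param ... passed to [coxnet()].
#' @return An object of class `cv_coxnet`: the full-data `fit`, `lambda`,
#'   `cvm`, `cvsd`, `lambda_min`, `lambda_1se`, `foldid`.
#' @export
cv_coxnet <- function(x, start = NULL, stop, event, weights = NULL,
                      alpha = 0.5, nfolds = 10L, foldid = NULL,
                      seed = 1L, fold_thresh = 1e-5, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(start)) start <- rep(-Inf, n)
  if (is.null(weights)) weights <- rep(1, n)
  if (nfolds < 2L) stop("nfolds must be at least 2")
  if (nfolds > sum(event)) stop("nfolds exceeds the number of events")
  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- integer(n)
    for (s in unique(event)) {
      idx <- which(event == s)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  }
  fit <- coxnet(x, start, stop, event, weights, alpha = alpha, ...)
  lambda <- fit$lambda

  dev <- matrix(NA_real_, nfolds, length(lambda))
  wn_all <- weights / sum(weights)
  prep_all <- cox_prep(start, stop, event, wn_all)
  for (k in seq_len(nfolds)) {
    inb <- foldid != k
    if (sum(event[inb]) < 2L) stop("a training fold has fewer than 2 events")
    fold_args <- list(...)
    fold_args$thresh <- fold_thresh
    fk <- do.call(coxnet, c(list(x[inb, , drop = FALSE], start[inb],
                                 stop[inb], event[inb], weights[inb],
                                 alpha = alpha, lambda = lambda),
                            fold_args))
    wn_inb <- weights[inb] / sum(weights[inb])
    prep_inb <- cox_prep(start[inb], stop[inb], event[inb], wn_inb)
    eta_all <- x %*% fk$beta
    eta_inb <- eta_all[inb, , drop = FALSE]
    for (l in seq_along(fk$lambda)) {  # fold path may truncate earlier
      ll_all <- cox_quant(prep_all, eta_all[, l],
                          loglik_only = TRUE)$loglik * sum(weights)
      ll_inb <- cox_quant(prep_inb, eta_inb[, l],
                          loglik_only = TRUE)$loglik * sum(weights[inb])
      dev[k, l] <- -2 * (ll_all - ll_inb)
    }
  }
  # restrict selection to lambdas fit by every fold
  complete <- colSums(is.na(dev)) == 0L
  if (!any(complete)) stop("no lambda was fit by every CV fold")
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2L, stats::sd) / sqrt(nfolds)
  l_min <- which(complete)[which.min(cvm[complete])]
  l_1se <- min(which(complete & cvm <= cvm[l_min] + cvsd[l_min]))
  structure(list(fit = fit, lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[l_min], lambda_1se = lambda[l_1se],
                 index_min = l_min, foldid = foldid, dev_folds = dev),
            class = "cv_coxnet")
}

#' @export
print.cv_coxnet <- function(x, ...) {
  cat(sprintf("cv_coxnet: %d-fold CV over %d lambdas\n",
              max(x$foldid), length(x$lambda)))
  cat(sprintf("  lambda_min = %.5g (%d nonzero), lambda_1se = %.5g (%d nonzero)\n",
              x$lambda_min, x$fit$df[x$index_min],
              x$lambda_1se, x$fit$df[match(x$lambda_1se, x$lambda)]))
  invisible(x)
}

#' @export
coef.cv_coxnet <- function(object, lambda = c("lambda_1se", "lambda_min"),
                           ...) {
  if (is.character(lambda)) lambda <- object[[match.arg(lambda)]]
  coef(object$fit, lambda = lambda)
}

#' @export
plot.cv_coxnet <- function(x, ...) {
  graphics::plot(log(x$lambda), x$cvm, type = "l",
                 xlab = expression(log(lambda)),
                 ylab = "CV partial-likelihood deviance", ...)
  graphics::arrows(log(x$lambda), x$cvm - x$cvsd, log(x$lambda),
                   x$cvm + x$cvsd, angle = 90, code = 3, length = 0.02,
                   col = "grey60")
  graphics::abline(v = log(x$lambda_min), lty = 2)
  invisible(x)
}
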