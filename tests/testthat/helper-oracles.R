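# Independent oracles, deliberately written from first principles (naive
# loops, full matrices) so they share no code with the package internals.

# Breslow log partial likelihood, gradient and full Hessian by direct
# enumeration of risk sets.  Supports (start, stop] intervals and weights.
pl_derivs <- function(beta, x, start, stop, event, w) {
  n <- nrow(x); p <- ncol(x)
  eta <- as.numeric(x %*% beta)
  r <- w * exp(eta)
  ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
  for (i in which(event == 1)) {
    t_i <- stop[i]
    at_risk <- which(start < t_i & stop >= t_i)
    s0 <- sum(r[at_risk])
    s1 <- colSums(r[at_risk] * x[at_risk, , drop = FALSE])
    s2 <- matrix(0, p, p)
    for (j in at_risk) s2 <- s2 + r[j] * tcrossprod(x[j, ])
    ll <- ll + w[i] * (eta[i] - log(s0))
    grad <- grad + w[i] * (x[i, ] - s1 / s0)
    hess <- hess - w[i] * (s2 / s0 - tcrossprod(s1 / s0))
  }
  list(loglik = ll, grad = grad, hess = hess)
}

# Unpenalized weighted Cox fit by full-Hessian Newton-Raphson.
newton_cox <- function(x, start, stop, event, w = rep(1, nrow(x)),
                       tol = 1e-12, maxit = 50) {
  beta <- numeric(ncol(x))
  for (it in seq_len(maxit)) {
    d <- pl_derivs(beta, x, start, stop, event, w)
    step <- solve(-d$hess, d$grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Ridge-penalized weighted Cox: minimizes -logPL_w/sum(w) + lam/2 ||b||^2
# on pre-standardized features, by Newton-Raphson.
ridge_newton_cox <- function(x, start, stop, event, w, lam,
                             tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(x))
  sw <- sum(w)
  for (it in seq_len(maxit)) {
    d <- pl_derivs(beta, x, start, stop, event, w)
    grad <- -d$grad / sw + lam * beta
    hess <- -d$hess / sw + lam * diag(ncol(x))
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Logistic regression by hand-coded IRLS (normal equations).
irls_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wt <- mu * (1 - mu)
    z <- eta + (y - mu) / wt
    beta_new <- solve(crossprod(X, wt * X), crossprod(X, wt * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

# AUC by brute-force all-pairs concordance with tie correction.
auc_bruteforce <- function(score, case) {
  xs <- score[case == 1]; ys <- score[case == 0]
  tot <- 0
  for (a in xs) for (b in ys)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

# Ordinary least squares via explicit normal equations.
ols_normal_eq <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Small simulated survival dataset with one standardized covariate.
sim_surv1 <- function(n, beta, seed, base = 0.1, cens = 0.07) {
  set.seed(seed)
  z <- rnorm(n)
  t_ev <- rexp(n, base * exp(beta * z))
  t_cn <- rexp(n, cens)
  list(z = z, time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
}
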