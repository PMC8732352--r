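test_that("penalty above lambda_max gives the all-zero model", {
  d <- sim_surv1(100, 0.6, seed = 1)
  x <- cbind(a = d$z, b = rnorm(100), c = rnorm(100))
  fit <- coxnet(x, stop = d$time, event = d$event, nlambda = 20)
  expect_equal(unname(fit$beta[, 1]), c(0, 0, 0))
  big <- coxnet(x, stop = d$time, event = d$event,
                lambda = c(10 * fit$lambda[1], 5 * fit$lambda[1]))
  expect_true(all(big$beta == 0))
})

test_that("the unpenalized limit matches a Newton-Raphson partial-likelihood oracle", {
  set.seed(2)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  lp <- x %*% c(0.7, -0.4, 0.2)
  t_ev <- rexp(n, 0.2 * exp(lp)); t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  fit <- coxnet(x, stop = time, event = event, weights = rep(1, n),
                lambda = c(1, 1e-7), thresh = 1e-10)
  oracle <- newton_cox(x, rep(-Inf, n), time, event)
  expect_equal(unname(fit$beta[, 2]), oracle, tolerance = 1e-4)
})

test_that("observation weights enter the partial likelihood correctly", {
  set.seed(3)
  n <- 80
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  t_ev <- rexp(n, 0.2 * exp(0.5 * x[, 1])); t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  w <- runif(n, 0.2, 3)
  fit <- coxnet(x, stop = time, event = event, weights = w,
                lambda = c(1, 1e-7), thresh = 1e-10)
  oracle <- newton_cox(x, rep(-Inf, n), time, event, w)
  expect_equal(unname(fit$beta[, 2]), oracle, tolerance = 1e-4)
})

test_that("the ridge limit matches a penalized Newton oracle", {
  set.seed(4)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  t_ev <- rexp(n, 0.2 * exp(0.6 * x[, 1])); t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  w <- rep(1, n)
  lam <- 0.05
  fit <- coxnet(x, stop = time, event = event, weights = w, alpha = 0,
                lambda = c(1, lam), thresh = 1e-11)
  wn <- w / sum(w)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- sqrt(colMeans(xc^2))
  xs <- sweep(xc, 2, scl, "/")
  oracle_std <- ridge_newton_cox(xs, rep(-Inf, n), time, event, wn, lam)
  expect_equal(unname(fit$beta[, 2]), unname(oracle_std / scl),
               tolerance = 1e-4)
})

test_that("KKT conditions hold along the automatic path", {
  d <- sim_surv1(150, 0.5, seed = 5)
  x <- cbind(d$z, matrix(rnorm(150 * 9), 150, 9))
  colnames(x) <- paste0("f", 1:10)
  w <- runif(150, 0.5, 2)
  fit <- coxnet(x, stop = d$time, event = d$event, weights = w, nlambda = 50)
  kkt <- coxnet_kkt(fit, x, stop = d$time, event = d$event, weights = w)
  expect_lt(max(kkt), 1e-6)
})

test_that("the penalized objective never increases during fitting", {
  d <- sim_surv1(120, 0.6, seed = 6)
  x <- cbind(d$z, matrix(rnorm(120 * 5), 120, 5))
  colnames(x) <- paste0("f", 1:6)
  fit <- coxnet(x, stop = d$time, event = d$event)
  expect_lt(fit$max_obj_increase, 1e-10)
  # objective along the path decreases as lambda decreases
  expect_true(all(diff(fit$obj) < 1e-10))
})

test_that("coefficients change continuously along the path", {
  d <- sim_surv1(200, 0.7, seed = 7)
  x <- cbind(d$z, matrix(rnorm(200 * 7), 200, 7))
  colnames(x) <- paste0("f", 1:8)
  fit <- coxnet(x, stop = d$time, event = d$event, nlambda = 100)
  jumps <- apply(abs(diff(t(fit$beta_std))), 1, max)
  expect_lt(max(jumps), 0.15)
})

test_that("rescaling one feature rescales its coefficient reciprocally", {
  set.seed(8)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  t_ev <- rexp(n, 0.2 * exp(0.5 * x[, 1])); t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  f1 <- coxnet(x, stop = time, event = event, lambda = c(1, 1e-7),
               thresh = 1e-10)
  x2 <- x; x2[, 1] <- 10 * x2[, 1]
  f2 <- coxnet(x2, stop = time, event = event, lambda = c(1, 1e-7),
               thresh = 1e-10)
  expect_equal(f2$beta["a", 2], f1$beta["a", 2] / 10, tolerance = 1e-6)
  expect_equal(f2$beta["b", 2], f1$beta["b", 2], tolerance = 1e-6)
})

test_that("path agrees with glmnet on a weighted right-censored problem", {
  set.seed(9)
  n <- 150
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  t_ev <- rexp(n, 0.2 * exp(0.6 * x[, 1] - 0.4 * x[, 2]))
  t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  w <- runif(n, 0.5, 2)
  fit <- coxnet(x, stop = time, event = event, weights = w, nlambda = 30)
  g <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                      weights = w, alpha = 0.5, lambda = fit$lambda,
                      thresh = 1e-12)
  expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 2e-4)
})

test_that("left truncation reproduces the age-timescale coxph fit", {
  set.seed(10)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  entry <- runif(n, 35, 60)
  t_ev <- rexp(n, 0.05 * exp(0.5 * x[, 1]))
  fu <- runif(n, 1, 10)
  event <- as.integer(t_ev <= fu)
  exit <- entry + pmin(t_ev, fu)
  fit <- coxnet(x, start = entry, stop = exit, event = event,
                lambda = c(1, 1e-7), thresh = 1e-10)
  cph <- survival::coxph(survival::Surv(entry, exit, event) ~ x,
                         ties = "breslow")
  expect_equal(unname(fit$beta[, 2]), unname(coef(cph)), tolerance = 1e-4)
})

test_that("cross-validation selects nothing on pure noise and finds a strong signal", {
  null_hits <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 150
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    time <- rexp(n, 0.15); event <- rbinom(n, 1, 0.7)
    cv <- cv_coxnet(x, stop = time, event = event, nfolds = 5, seed = s,
                    nlambda = 40)
    if (sum(coef(cv) != 0) == 0L) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits, 9L)

  strong_hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 400
    x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
    t_ev <- rexp(n, 0.1 * exp(log(3) * x[, 1]))
    t_cn <- rexp(n, 0.05)
    time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
    cv <- cv_coxnet(x, stop = time, event = event, nfolds = 5, seed = s,
                    nlambda = 40)
    if (coef(cv)["f1"] != 0) strong_hits <- strong_hits + 1L
  }
  expect_gte(strong_hits, 10L)
})

test_that("the CV curve is invariant to fold label permutation", {
  d <- sim_surv1(120, 0.5, seed = 11)
  x <- cbind(d$z, matrix(rnorm(120 * 4), 120, 4))
  colnames(x) <- paste0("f", 1:5)
  foldid <- sample(rep_len(1:5, 120))
  cv1 <- cv_coxnet(x, stop = d$time, event = d$event, nfolds = 5,
                   foldid = foldid, nlambda = 30)
  relabel <- c(3L, 5L, 1L, 2L, 4L)[foldid]
  cv2 <- cv_coxnet(x, stop = d$time, event = d$event, nfolds = 5,
                   foldid = relabel, nlambda = 30)
  expect_equal(cv1$cvm, cv2$cvm, tolerance = 1e-12)
  expect_equal(cv1$lambda_min, cv2$lambda_min)
})

test_that("fits are deterministic under a fixed seed", {
  d <- sim_surv1(100, 0.5, seed = 12)
  x <- cbind(d$z, matrix(rnorm(100 * 4), 100, 4))
  colnames(x) <- paste0("f", 1:5)
  cv1 <- cv_coxnet(x, stop = d$time, event = d$event, nfolds = 4, seed = 77,
                   nlambda = 30)
  cv2 <- cv_coxnet(x, stop = d$time, event = d$event, nfolds = 4, seed = 77,
                   nlambda = 30)
  expect_identical(cv1$foldid, cv2$foldid)
  expect_identical(coef(cv1), coef(cv2))
})

test_that("input validation catches contract violations", {
  d <- sim_surv1(50, 0.5, seed = 13)
  x <- cbind(a = d$z, b = rnorm(50))
  expect_error(coxnet(x, stop = d$time, event = rep(0, 50)), "2 events")
  expect_error(coxnet(x, stop = d$time, event = d$event,
                      lambda = c(0.1, 0.2)), "decreasing")
  expect_error(coxnet(x, stop = d$time, event = d$event,
                      weights = rep(-1, 50)), "nonnegative")
  expect_error(coxnet(x, stop = d$time, event = d$event, alpha = 2), "alpha")
  expect_error(cv_coxnet(x, stop = d$time, event = d$event,
                         nfolds = sum(d$event) + 1), "exceeds")
})
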