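# ---- standardized residuals -----------------------------------------------

test_that("constant covariates reduce residualization to centering/scaling", {
  set.seed(1)
  sc <- stats::setNames(rnorm(50, 10, 2), sprintf("S%02d", 1:50))
  ref <- names(sc)[1:30]
  rs <- standardized_residuals(sc, covariates = NULL, reference_ids = ref)
  want <- (sc - mean(sc[ref])) / sd(sc[ref] - mean(sc[ref]))
  expect_equal(rs$residual_standardized, want, tolerance = 1e-12)
  expect_lt(abs(mean(rs$residual_standardized[ref])), 1e-10)
  expect_equal(sd(rs$residual_standardized[ref]), 1, tolerance = 1e-10)
})

test_that("a score exactly linear in covariates is reported degenerate", {
  set.seed(2)
  cov <- data.frame(age = runif(40, 35, 74))
  sc <- stats::setNames(2 * cov$age + 3, sprintf("S%02d", 1:40))
  expect_error(standardized_residuals(sc, cov), "degenerate")
})

test_that("residualization matches a normal-equations + SD oracle", {
  set.seed(3)
  n <- 120
  cov <- data.frame(age = runif(n, 35, 74), bmi = rnorm(n, 27, 5),
                    meno = rbinom(n, 1, 0.6))
  sc <- stats::setNames(0.1 * cov$age - 0.2 * cov$bmi + rnorm(n),
                        sprintf("S%03d", 1:n))
  ref <- names(sc)[1:80]
  rs <- standardized_residuals(sc, cov, reference_ids = ref)
  cf <- ols_normal_eq(as.matrix(cov[1:80, ]), sc[1:80])
  res <- sc - (cf[1] + as.matrix(cov) %*% cf[-1])
  want <- res / sd(res[1:80])
  expect_equal(rs$residual_standardized, stats::setNames(drop(want), names(sc)),
               tolerance = 1e-10)
  # orthogonality to every adjustment covariate within the reference set
  for (v in names(cov))
    expect_lt(abs(cor(rs$residual_standardized[ref], cov[[v]][1:80])), 1e-10)
})

test_that("collinear covariates are named in the rank-deficiency error", {
  set.seed(4)
  cov <- data.frame(a = rnorm(30), b = rnorm(30))
  cov$c <- cov$a + cov$b
  sc <- stats::setNames(rnorm(30), sprintf("S%02d", 1:30))
  expect_error(standardized_residuals(sc, cov), "collinear")
})

# ---- case-cohort Cox -------------------------------------------------------

make_cc_fixture <- function(seed, n = 3000, beta = log(1.8), f = 0.15,
                            base = 0.004) {
  set.seed(seed)
  z <- rnorm(n)
  entry <- runif(n, 35, 74)
  t_ev <- rexp(n, base * exp(beta * z))
  fu <- runif(n, 1, 9.4)
  event <- as.integer(t_ev <= fu)
  exit <- entry + pmin(t_ev, fu)
  ph <- data.frame(sample_id = sprintf("S%05d", 1:n), event = event)
  cc <- apply_case_cohort_sampling(ph, f, seed = seed)
  idx <- match(cc$sample_id, ph$sample_id)
  des <- cbind(cc, age_entry = entry[idx], age_exit = exit[idx])
  attr(des, "sampling_fraction") <- f
  list(design = des, z = z[idx], full = data.frame(
    entry = entry, exit = exit, event = event, z = z))
}

test_that("sampling fraction 1 equals the full-cohort left-truncated Cox fit", {
  d <- make_cc_fixture(5, n = 800, f = 1)
  res <- casecohort_cox(cbind(z = d$z), d$design)
  cph <- survival::coxph(survival::Surv(entry, exit, event) ~ z,
                         data = d$full, ties = "breslow")
  expect_equal(log(res$estimate), unname(coef(cph)), tolerance = 1e-6)
})

test_that("latency exclusion drops early events and short follow-up", {
  d <- make_cc_fixture(6, n = 2000, f = 0.3)
  res0 <- casecohort_cox(cbind(z = d$z), d$design)
  res2 <- casecohort_cox(cbind(z = d$z), d$design,
                         latency_exclusion_years = 2)
  keep <- d$design$age_exit > d$design$age_entry + 2
  expect_equal(res2$n, sum(keep))
  expect_equal(res2$events, sum(d$design$case[keep]))
  expect_lt(res2$n, res0$n)
  expect_lt(res2$events, res0$events)
})

test_that("joint models report one row per predictor", {
  d <- make_cc_fixture(7, n = 1500, f = 0.3)
  other <- rnorm(nrow(d$design))
  res <- casecohort_cox(cbind(score = d$z, prs = other), d$design,
                        joint = TRUE)
  expect_equal(res$predictor, c("score", "prs"))
  expect_true(all(res$model == "multivariable"))
  expect_true(all(res$conf_low < res$estimate & res$estimate < res$conf_high))
  # P matches the normal reference for the reported Z
  expect_equal(res$p, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
})

# ---- tertiles --------------------------------------------------------------

test_that("tertile cutpoints equal the reference empirical quantiles", {
  d <- make_cc_fixture(8, n = 2000, f = 0.3)
  tert <- tertile_association(d$z, d$design)
  ref <- d$design$subcohort == 1 & d$design$case == 0
  expect_equal(tert$cutpoints,
               unname(quantile(d$z[ref], c(1, 2) / 3)), tolerance = 1e-12)
  expect_equal(nrow(tert$tertiles), 2)
})

test_that("tertile hazard ratios are monotone under a strong effect", {
  mono <- 0L
  for (s in 1:5) {
    d <- make_cc_fixture(800 + s, n = 4000, beta = 0.59, f = 0.2)
    tert <- tertile_association(d$z, d$design)
    hr <- tert$tertiles$estimate
    if (hr[2] > hr[1] && hr[1] > 1) mono <- mono + 1L
  }
  expect_gte(mono, 4L)
})

# ---- logistic validation and OPERA ----------------------------------------

test_that("logistic validation matches a hand-coded IRLS oracle", {
  set.seed(9)
  n <- 330
  sc <- rnorm(n)
  case <- rbinom(n, 1, plogis(-0.3 + 0.75 * sc))
  res <- logistic_validation(sc, case)
  oracle <- irls_logistic(matrix(sc), case)
  expect_equal(log(res$estimate), oracle[2], tolerance = 1e-8)
  expect_equal(res$type, "OR")
})

test_that("logistic recovery at the external-validation scale is unbiased", {
  est <- vapply(1:100, function(s) {
    set.seed(4000 + s)
    sc <- rnorm(330)
    case <- rbinom(330, 1, plogis(0.75 * sc))
    log(logistic_validation(sc, case)$estimate)
  }, 0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.75), 3 * mc_se)
})

test_that("complete separation is reported rather than estimated", {
  sc <- c(rnorm(20, -3), rnorm(20, 3))
  case <- rep(c(0, 1), each = 20)
  res <- logistic_validation(sc, case)
  expect_equal(res$model, "separated")
  expect_true(is.na(res$estimate))
})

test_that("OPERA on a lone standardized predictor equals exp(logistic coefficient)", {
  set.seed(10)
  n <- 400
  sc <- as.numeric(scale(rnorm(n)))
  case <- rbinom(n, 1, plogis(0.5 * sc))
  op <- opera(cbind(score = sc), case)
  g <- glm(case ~ sc, family = binomial())
  expect_equal(op$estimates$estimate, unname(exp(coef(g)[2])),
               tolerance = 1e-12)
  expect_equal(op$loglik, as.numeric(logLik(g)), tolerance = 1e-10)
  expect_gte(op$lr_chisq, 0)
  expect_equal(op$df, 1L)
})

test_that("univariable and multivariable OPERAs agree for independent predictors", {
  set.seed(11)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n)
  case <- rbinom(n, 1, plogis(0.4 * a + 0.3 * b))
  uni_a <- opera(cbind(a = a), case)$estimates$estimate
  multi <- opera(cbind(a = a, b = b), case)$estimates
  expect_lt(abs(log(uni_a) - log(multi$estimate[1])), 0.1)
})

test_that("likelihood-ratio chi-squares are additive-consistent under nesting", {
  set.seed(12)
  n <- 600
  P <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  case <- rbinom(n, 1, plogis(0.3 * P[, 1] - 0.2 * P[, 3]))
  chis_all <- opera(P, case)$lr_chisq
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_gte(chis_all + 1e-8, opera(P[, pair], case)$lr_chisq)
})

# ---- AUC and DeLong --------------------------------------------------------

test_that("AUC equals the brute-force all-pairs concordance", {
  set.seed(13)
  for (s in 1:5) {
    n <- 80
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    case <- rbinom(n, 1, 0.4)
    if (length(unique(case)) < 2) next
    expect_equal(auc(sc, case)$auc, auc_bruteforce(sc, case),
                 tolerance = 1e-12)
  }
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1.0)
  expect_error(auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC and DeLong agree with the pROC reference implementation", {
  set.seed(14)
  n <- 150
  s1 <- rnorm(n); case <- rbinom(n, 1, plogis(s1))
  s2 <- s1 + rnorm(n, 0, 2)
  a <- auc(s1, case)
  r <- pROC::roc(case, s1, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(c(a$conf_low, a$conf_high), ci[c(1, 3)], tolerance = 1e-9)
  dt <- delong_test(s1, s2, case)
  r2 <- pROC::roc(case, s2, quiet = TRUE, direction = "<")
  pr <- pROC::roc.test(r, r2, method = "delong", paired = TRUE)
  expect_equal(dt$p, pr$p.value, tolerance = 1e-9)
})

test_that("sequential AUC is consistent with auc() on fitted probabilities", {
  set.seed(15)
  n <- 500
  rf <- data.frame(bmi = rnorm(n), meno = rbinom(n, 1, 0.6))
  prs <- rnorm(n); sc <- rnorm(n)
  case <- rbinom(n, 1, plogis(0.3 * prs + 0.5 * sc))
  sa <- sequential_auc(rf, prs, sc, case)
  expect_equal(nrow(sa), 3)
  fit1 <- glm(case ~ ., data = rf, family = binomial())
  expect_equal(sa$auc[1], auc(fit1$fitted.values, case)$auc,
               tolerance = 1e-12)
  expect_true(is.na(sa$p_vs_previous[1]))
  expect_false(anyNA(sa$p_vs_previous[-1]))
})

# ---- heterogeneity and effect modification --------------------------------

test_that("heterogeneity test is label-symmetric and supports 3 subtypes", {
  set.seed(16)
  n <- 300
  sc <- rnorm(n)
  sub <- ifelse(rbinom(n, 1, plogis(0.5 * sc)) == 1, "invasive", "DCIS")
  h1 <- heterogeneity_test(sc, sub)
  h2 <- heterogeneity_test(sc, factor(sub, levels = c("invasive", "DCIS")))
  expect_equal(h1$p, h2$p, tolerance = 1e-8)
  expect_equal(unname(h1$estimates), -unname(h2$estimates), tolerance = 1e-6)
  sub3 <- sample(c("a", "b", "c"), n, replace = TRUE)
  h3 <- heterogeneity_test(sc, sub3)
  expect_equal(h3$df, 2L)
  expect_true(h3$p > 0 && h3$p <= 1)
  expect_error(heterogeneity_test(sc, rep("x", n)), "2 subtype")
})

test_that("two identical strata give equal per-stratum estimates", {
  d <- make_cc_fixture(17, n = 1500, f = 0.3)
  des2 <- rbind(d$design, transform(d$design,
                                    sample_id = paste0(sample_id, "_b")))
  attr(des2, "sampling_fraction") <- 0.3
  z2 <- c(d$z, d$z)
  stratum <- rep(c("s1", "s2"), each = nrow(d$design))
  em <- effect_modification(z2, des2, stratum)
  expect_equal(em$per_stratum$estimate[1], em$per_stratum$estimate[2],
               tolerance = 1e-8)
  expect_gt(em$interaction_p, 0.99)
})

# ---- correlation report ----------------------------------------------------

test_that("correlations match the covariance formula and self-correlation is 1", {
  set.seed(18)
  n <- 100
  sc <- stats::setNames(rnorm(n), sprintf("S%03d", 1:n))
  comp <- data.frame(self = sc, other = rnorm(n))
  cr <- correlation_report(sc, comp)
  expect_equal(cr$r[cr$variable == "self"], 1)
  r_oracle <- sum((sc - mean(sc)) * (comp$other - mean(comp$other))) /
    ((n - 1) * sd(sc) * sd(comp$other))
  expect_equal(cr$r[cr$variable == "other"], r_oracle, tolerance = 1e-12)
  expect_error(correlation_report(sc, data.frame(k = rep(1, n))),
               "zero-variance")
})

test_that("null correlations stay inside the sampling band at subcohort scale", {
  inside <- 0L
  for (s in 1:40) {
    set.seed(5000 + s)
    sc <- stats::setNames(rnorm(375), sprintf("S%03d", 1:375))
    cr <- correlation_report(sc, data.frame(prs = rnorm(375)))
    if (abs(cr$r) < 0.15) inside <- inside + 1L
  }
  expect_gte(inside, 38L)
})
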