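# Validation statistics for methylation risk scores in case-cohort and
# nested case-control samples.

assoc_row <- function(predictor, type, est, se, n, events, model) {
  z <- est / se
  data.frame(predictor = predictor, type = type,
             estimate = exp(est),
             conf_low = exp(est - 1.959964 * se),
             conf_high = exp(est + 1.959964 * se),
             z = z, p = 2 * stats::pnorm(-abs(z)),
             n = n, events = events, model = model,
             stringsAsFactors = FALSE)
}

#' Standardized covariate-adjusted residuals
#'
#' Regresses a score on a covariate set by least squares within a reference
#' set (conventionally the random subcohort), computes residuals
#' (observed - predicted) for all samples, and divides by the standard
#' deviation of the reference-set residuals. Within the reference set the
#' standardized residuals have mean 0 and SD 1 and are orthogonal to every
#' covariate. Passing an empty covariate set (or all-constant covariates)
#' reduces to centering and scaling by the reference distribution; passing
#' only age gives the age-adjusted standardization used for external
#' validation samples without questionnaire data.
#'
#' @param score named per-sample numeric score.
#' @param covariates data.frame or matrix of adjustment covariates, same
#'   rows/order as `score` (an intercept is added internally).
#' @param reference_ids names (or indices) of the reference samples used to
#'   fit the adjustment regression and the SD; default all samples.
#' @return An object of class `residualized_score`: list with `sample_ids`,
#'   `raw_score`, `residual_standardized`, `adjustment_covariates`,
#'   `reference_ids`, `sd_reference`.
#' @export
standardized_residuals <- function(score, covariates = NULL,
                                   reference_ids = NULL) {
  ids <- names(score) %||% as.character(seq_along(score))
  ref <- if (is.null(reference_ids)) seq_along(score)
         else if (is.character(reference_ids)) match(reference_ids, ids)
         else reference_ids
  if (anyNA(ref)) stop("reference_ids not found among samples")
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    X <- matrix(1, length(score), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(score))
      stop("covariates must have one row per sample")
    X <- stats::model.matrix(~ ., data = covariates)
  }
  if (length(ref) <= ncol(X))
    stop("reference set must exceed the number of covariates + 1")
  qr_ref <- qr(X[ref, , drop = FALSE])
  if (qr_ref$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_ref$pivot[(qr_ref$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  coefs <- qr.coef(qr_ref, score[ref])
  resid <- as.numeric(score - X %*% coefs)
  s <- stats::sd(resid[ref])
  if (!is.finite(s) || s <= 1e-8 * max(stats::sd(score[ref]), 1e-300))
    stop("degenerate residuals: score is exactly linear in the covariates")
  structure(list(sample_ids = ids, raw_score = as.numeric(score),
                 residual_standardized = stats::setNames(resid / s, ids),
                 adjustment_covariates = setdiff(colnames(X), "(Intercept)"),
                 reference_ids = ids[ref], sd_reference = s),
            class = "residualized_score")
}

#' @export
print.residualized_score <- function(x, ...) {
  cat(sprintf("residualized_score: %d samples, %d covariate term(s), %d reference samples\n",
              length(x$sample_ids), length(x$adjustment_covariates),
              length(x$reference_ids)))
  invisible(x)
}

# Coerce predictor input (vector / residualized_score / matrix / data.frame)
# to a plain numeric matrix with one column per predictor.
as_predictor_matrix <- function(predictors, n) {
  if (inherits(predictors, "residualized_score"))
    predictors <- predictors$residual_standardized
  if (is.null(dim(predictors))) {
    nm <- deparse(substitute(predictors))
    predictors <- matrix(predictors, ncol = 1L,
                         dimnames = list(NULL, "score"))
  }
  predictors <- as.matrix(predictors)
  if (nrow(predictors) != n)
    stop("predictors must have one row per design row")
  nm <- colnames(predictors)
  if (is.null(nm)) nm <- rep("", ncol(predictors))
  blank <- is.na(nm) | nm == ""
  nm[blank] <- paste0("x", which(blank))
  colnames(predictors) <- nm
  predictors
}

#' Case-cohort Cox association with Barlow weights
#'
#' Fits counting-process Cox models on `(start, stop]` age intervals built
#' by [barlow_weights()], with age as the timescale (so hazard ratios are
#' fully age-adjusted), Barlow's inverse-sampling-fraction weights, and a
#' robust sandwich variance aggregated by woman. With
#' `latency_exclusion_years > 0`, any woman whose follow-up ends within the
#' window is excluded and at-risk entry is advanced by the window, guarding
#' against clinically occult disease at blood draw.
#'
#' @param predictors per-woman predictor(s): a numeric vector, a
#'   [standardized_residuals()] object, or a matrix/data.frame (one row per
#'   design row, aligned with `design`).
#' @param design data.frame with one row per woman and columns `sample_id`,
#'   `case`, `subcohort`, `age_entry`, `age_exit` (event = case).
#' @param sampling_fraction subcohort sampling fraction (default: design
#'   attribute).
#' @param latency_exclusion_years years of early follow-up to exclude
#'   (default 0).
#' @param joint fit all predictors in a single model (`TRUE`) or one
#'   univariate model per predictor (`FALSE`, default).
#' @param eps Barlow event-interval width in years (default 0.001).
#' @return A data.frame of association results, one row per predictor:
#'   hazard ratio, 95% CI, robust Z, two-sided P, n and events.
#' @export
casecohort_cox <- function(predictors, design, sampling_fraction = NULL,
                           latency_exclusion_years = 0, joint = FALSE,
                           eps = 0.001) {
  n <- nrow(design)
  P <- as_predictor_matrix(predictors, n)
  lat <- latency_exclusion_years
  keep <- design$age_exit > design$age_entry + lat
  d2 <- design[keep, , drop = FALSE]
  P <- P[keep, , drop = FALSE]
  if (lat > 0) d2$age_entry <- d2$age_entry + lat
  if (sum(d2$case) < 2) stop("fewer than 2 events after latency exclusion")
  if (is.null(sampling_fraction))
    sampling_fraction <- attr(design, "sampling_fraction")
  bw <- barlow_weights(d2, sampling_fraction, eps = eps)
  idx <- match(bw$sample_id, d2$sample_id)
  dat <- cbind(bw, as.data.frame(P)[idx, , drop = FALSE])
  names(dat)[(ncol(bw) + 1L):ncol(dat)] <- colnames(P)

  fit_one <- function(vars, label) {
    f <- stats::as.formula(paste(
      "survival::Surv(start, stop, event) ~",
      paste(sprintf("`%s`", vars), collapse = " + ")))
    fit <- survival::coxph(f, data = dat, weights = dat$weight,
                           cluster = dat$sample_id, robust = TRUE)
    se <- sqrt(diag(fit$var))
    do.call(rbind, lapply(seq_along(vars), function(j)
      assoc_row(vars[j], "HR", fit$coefficients[j], se[j],
                n = nrow(d2), events = sum(d2$case), model = label)))
  }
  out <- if (joint && ncol(P) > 1L) fit_one(colnames(P), "multivariable")
         else do.call(rbind, lapply(colnames(P), function(v)
           fit_one(v, "univariate")))
  rownames(out) <- NULL
  out
}

#' Tertile-based case-cohort association with trend test
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles of the score within a
#' reference distribution (default: the random subcohort noncases). Hazard
#' ratios for T2 and T3 versus T1 come from the Barlow-weighted Cox model on
#' indicator contrasts; the trend P is the robust Wald test on an ordinal
#' 0/1/2 coding.
#'
#' @param score per-woman score aligned with `design` rows.
#' @inheritParams casecohort_cox
#' @param reference_ids sample IDs anchoring the cutpoints (default:
#'   subcohort noncases in the design).
#' @return List with `tertiles` (association data.frame: T2 vs T1, T3 vs
#'   T1), `trend_p`, and `cutpoints`.
#' @export
tertile_association <- function(score, design, sampling_fraction = NULL,
                                reference_ids = NULL, eps = 0.001) {
  if (inherits(score, "residualized_score"))
    score <- score$residual_standardized
  ref <- if (is.null(reference_ids))
    design$subcohort == 1L & design$case == 0L
  else design$sample_id %in% reference_ids
  if (!any(ref)) stop("empty reference set for tertile cutpoints")
  cut3 <- stats::quantile(score[ref], c(1, 2) / 3, names = FALSE)
  tert <- 1L + (score > cut3[1]) + (score > cut3[2])
  if (any(tapply(design$case, tert, sum, default = 0L) == 0))
    stop("a tertile contains no events")
  ind <- cbind(T2 = as.numeric(tert == 2L), T3 = as.numeric(tert == 3L))
  assoc <- casecohort_cox(ind, design, sampling_fraction, joint = TRUE,
                          eps = eps)
  assoc$predictor <- c("T2 vs T1", "T3 vs T1")
  trend <- casecohort_cox(cbind(trend = as.numeric(tert - 1L)), design,
                          sampling_fraction, eps = eps)
  list(tertiles = assoc, trend_p = trend$p, cutpoints = cut3)
}

#' Unconditional logistic validation in a case-control sample
#'
#' Maximum-likelihood logistic regression of case status on a (typically
#' age-adjusted, standardized) score; odds ratio per unit (per SD when the
#' score is standardized) with a Wald CI. Complete separation is reported
#' rather than estimated.
#'
#' @param score per-sample score (vector or [standardized_residuals()]).
#' @param case 0/1 case status.
#' @return One association data.frame row (type `"OR"`), or, under complete
#'   separation, a row of `NA` estimates with `model = "separated"`.
#' @export
logistic_validation <- function(score, case) {
  if (inherits(score, "residualized_score"))
    score <- score$residual_standardized
  case <- as.integer(case)
  if (length(unique(case)) < 2L) stop("both classes must be present")
  fit <- suppressWarnings(stats::glm(case ~ score, family = stats::binomial()))
  b <- stats::coef(fit)[["score"]]
  se <- sqrt(diag(stats::vcov(fit)))[["score"]]
  if (!fit$converged || abs(b) > 15 || se > 100)
    return(data.frame(predictor = "score", type = "OR", estimate = NA_real_,
                      conf_low = NA_real_, conf_high = NA_real_,
                      z = NA_real_, p = NA_real_, n = length(case),
                      events = sum(case), model = "separated",
                      stringsAsFactors = FALSE))
  assoc_row("score", "OR", b, se, n = length(case), events = sum(case),
            model = "logistic")
}

#' Odds ratio per adjusted standard deviation (OPERA)
#'
#' The risk gradient of one or more covariate-residualized, standardized
#' predictors: a joint logistic regression of case status on the predictor
#' set, reporting the OR per adjusted SD for each predictor, the model log
#' likelihood, and the likelihood-ratio chi-square (with DF = number of
#' predictors) against the intercept-only model. For a lone pre-standardized
#' predictor the OPERA equals `exp` of its logistic coefficient.
#'
#' @param predictors vector, [standardized_residuals()] object, or matrix /
#'   data.frame of pre-residualized standardized predictors (for age itself,
#'   residualize on all risk factors except age).
#' @param case 0/1 case status.
#' @return An object of class `opera_result`: list with `estimates` (per
#'   predictor OR, CI, Z, P), `loglik`, `loglik_null`, `lr_chisq`, `df`,
#'   `lr_p`.
#' @export
opera <- function(predictors, case) {
  case <- as.integer(case)
  P <- as_predictor_matrix(predictors, length(case))
  if (length(unique(case)) < 2L) stop("both classes must be present")
  df_fit <- as.data.frame(P)
  names(df_fit) <- make.names(names(df_fit))
  fit <- stats::glm(case ~ ., data = df_fit, family = stats::binomial())
  fit0 <- stats::glm(case ~ 1, family = stats::binomial())
  se <- sqrt(diag(stats::vcov(fit)))
  # coefficients follow column order after the intercept
  est <- do.call(rbind, lapply(seq_len(ncol(P)), function(j)
    assoc_row(colnames(P)[j], "OPERA", stats::coef(fit)[[j + 1L]],
              se[[j + 1L]], n = length(case), events = sum(case),
              model = "opera")))
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  chisq <- 2 * (ll - ll0)
  structure(list(estimates = est, loglik = ll, loglik_null = ll0,
                 lr_chisq = chisq, df = ncol(P),
                 lr_p = stats::pchisq(chisq, ncol(P), lower.tail = FALSE)),
            class = "opera_result")
}

#' @export
print.opera_result <- function(x, ...) {
  cat(sprintf("OPERA (odds ratio per adjusted SD); log lik %.1f (null %.1f), LR chi2 %.1f on %d df\n",
              x$loglik, x$loglik_null, x$lr_chisq, x$df))
  print(x$estimates[, c("predictor", "estimate", "conf_low", "conf_high",
                        "p")], digits = 3)
  invisible(x)
}

# DeLong placements: V10 (per case) and V01 (per noncase).
delong_placements <- function(score, case) {
  x <- score[case == 1L]; y <- score[case == 0L]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' AUC computed as the Mann-Whitney probability of concordance with the
#' standard tie correction (ties count 1/2); the CI uses the DeLong
#' placement variance, truncated to \[0, 1\].
#'
#' @param score predicted risk (higher = more case-like).
#' @param case 0/1 case status (both classes required).
#' @param label model label carried into the result.
#' @return An object of class `auc_result`: list with `label`, `auc`, `se`,
#'   `conf_low`, `conf_high`, `n_case`, `n_noncase`.
#' @export
auc <- function(score, case, label = "model") {
  case <- as.integer(case)
  if (length(unique(case)) < 2L) stop("both classes must be present")
  pl <- delong_placements(score, case)
  v <- stats::var(pl$v10) / pl$n1 + stats::var(pl$v01) / pl$n0
  se <- sqrt(v)
  structure(list(label = label, auc = pl$auc, se = se,
                 conf_low = max(0, pl$auc - 1.959964 * se),
                 conf_high = min(1, pl$auc + 1.959964 * se),
                 n_case = pl$n1, n_noncase = pl$n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC [%s] = %.3f (95%% CI %.3f, %.3f); %d cases / %d noncases\n",
              x$label, x$auc, x$conf_low, x$conf_high, x$n_case, x$n_noncase))
  invisible(x)
}

#' Paired DeLong test for the difference of two AUCs
#'
#' Both scores must be computed on the same samples; the covariance of the
#' two AUCs is estimated from the paired DeLong placements.
#'
#' @param score1,score2 two predicted-risk vectors on identical samples.
#' @param case 0/1 case status.
#' @return List with `auc1`, `auc2`, `diff`, `se_diff`, `z`, `p` (two-sided).
#' @export
delong_test <- function(score1, score2, case) {
  case <- as.integer(case)
  p1 <- delong_placements(score1, case)
  p2 <- delong_placements(score2, case)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / p1$n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / p1$n0
  d <- p1$auc - p2$auc
  z <- if (v > 0) d / sqrt(v) else 0
  list(auc1 = p1$auc, auc2 = p2$auc, diff = d, se_diff = sqrt(max(v, 0)),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sequential AUC comparison of nested risk models
#'
#' Fits nested logistic models - questionnaire risk factors alone; plus
#' PRS; plus the methylation score - computes each model's in-sample AUC
#' from its fitted probabilities, and the paired DeLong P for each
#' consecutive comparison.
#'
#' @param risk_factors data.frame/matrix of questionnaire risk factors.
#' @param prs per-sample polygenic risk score (or `NULL` to skip that rung).
#' @param score per-sample methylation score (or `NULL`).
#' @param case 0/1 case status.
#' @return data.frame with one row per model: `model`, `auc`, `conf_low`,
#'   `conf_high`, `p_vs_previous` (paired DeLong, `NA` for the first row).
#' @export
sequential_auc <- function(risk_factors, prs, score, case) {
  case <- as.integer(case)
  base <- as.data.frame(risk_factors)
  stages <- list("RFs" = base)
  if (!is.null(prs)) stages[["RFs + PRS"]] <- cbind(base, prs = prs)
  if (!is.null(score)) {
    with_prs <- if (!is.null(prs)) cbind(base, prs = prs) else base
    stages[[if (!is.null(prs)) "RFs + PRS + mBCRS" else "RFs + mBCRS"]] <-
      cbind(with_prs, mbcrs = score)
  }
  fits <- lapply(stages, function(d)
    stats::glm(case ~ ., data = d, family = stats::binomial())$fitted.values)
  out <- data.frame(model = names(stages),
                    auc = NA_real_, conf_low = NA_real_,
                    conf_high = NA_real_, p_vs_previous = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(fits)) {
    a <- auc(fits[[i]], case, label = names(stages)[i])
    out$auc[i] <- a$auc
    out$conf_low[i] <- a$conf_low
    out$conf_high[i] <- a$conf_high
    if (i > 1L)
      out$p_vs_previous[i] <- delong_test(fits[[i]], fits[[i - 1L]], case)$p
  }
  out
}

#' Case-only test of etiologic heterogeneity
#'
#' Regresses case subtype on the score among cases only: logistic for two
#' subtype levels, polytomous (multinomial) for more. The heterogeneity P is
#' the Wald test on the score coefficient(s).
#'
#' @param score per-case score.
#' @param subtype per-case subtype labels (>= 2 levels).
#' @return List with `p`, `statistic`, `df`, `levels`, and the per-level
#'   log-odds `estimates` (relative to the reference level).
#' @export
heterogeneity_test <- function(score, subtype) {
  if (inherits(score, "residualized_score"))
    score <- score$residual_standardized
  subtype <- droplevels(factor(subtype))
  if (nlevels(subtype) < 2L) stop("need at least 2 subtype levels")
  if (nlevels(subtype) == 2L) {
    y <- as.integer(subtype) - 1L
    fit <- stats::glm(y ~ score, family = stats::binomial())
    b <- stats::coef(fit)[["score"]]
    se <- sqrt(diag(stats::vcov(fit)))[["score"]]
    z <- b / se
    list(p = 2 * stats::pnorm(-abs(z)), statistic = z^2, df = 1L,
         levels = levels(subtype),
         estimates = stats::setNames(b, levels(subtype)[2L]))
  } else {
    fit <- nnet::multinom(subtype ~ score, trace = FALSE)
    cf <- stats::coef(fit)
    b <- cf[, "score"]
    V <- stats::vcov(fit)
    sel <- grep(":score$|^score$", rownames(V))
    Vb <- V[sel, sel, drop = FALSE]
    stat <- drop(t(b) %*% solve(Vb, b))
    df <- length(b)
    list(p = stats::pchisq(stat, df, lower.tail = FALSE), statistic = stat,
         df = df, levels = levels(subtype), estimates = b)
  }
}

#' Effect modification of a score association across strata
#'
#' Per-stratum Barlow-weighted Cox fits plus a pooled model with
#' stratum-specific baseline hazards and score-by-stratum product terms;
#' the interaction P is the robust Wald test on the product term(s).
#'
#' @param score per-woman score aligned with `design` rows.
#' @inheritParams casecohort_cox
#' @param stratum per-woman stratum labels.
#' @return List with `per_stratum` (association data.frame, one row per
#'   stratum) and `interaction_p`.
#' @export
effect_modification <- function(score, design, stratum,
                                sampling_fraction = NULL, eps = 0.001) {
  if (inherits(score, "residualized_score"))
    score <- score$residual_standardized
  stratum <- droplevels(factor(stratum))
  if (nlevels(stratum) < 2L) stop("need at least 2 strata")
  if (is.null(sampling_fraction))
    sampling_fraction <- attr(design, "sampling_fraction")
  per <- do.call(rbind, lapply(levels(stratum), function(s) {
    sel <- stratum == s
    if (sum(design$case[sel]) == 0L) stop("stratum without events: ", s)
    r <- casecohort_cox(cbind(score = score[sel]),
                        design[sel, , drop = FALSE], sampling_fraction,
                        eps = eps)
    r$predictor <- s
    r
  }))
  rownames(per) <- NULL

  bw <- barlow_weights(design, sampling_fraction, eps = eps)
  idx <- match(bw$sample_id, design$sample_id)
  dat <- cbind(bw, score = score[idx], stratum = stratum[idx])
  fit <- survival::coxph(
    survival::Surv(start, stop, event) ~ score * stratum +
      survival::strata(stratum),
    data = dat, weights = dat$weight, cluster = dat$sample_id,
    robust = TRUE)
  cf <- stats::coef(fit)
  sel <- grep("^score:", names(cf))
  V <- fit$var[sel, sel, drop = FALSE]
  stat <- drop(t(cf[sel]) %*% solve(V, cf[sel]))
  list(per_stratum = per,
       interaction_p = stats::pchisq(stat, length(sel), lower.tail = FALSE))
}

#' Pearson correlation report for a score against companion variables
#'
#' @param score named per-sample score.
#' @param companions data.frame of companion variables (PRS, age, risk
#'   factors, time to diagnosis, ...), same rows/order as `score`.
#' @param reference_ids sample names defining the reporting subset (e.g. the
#'   random subcohort, or cases only for time-to-diagnosis); default all.
#' @return data.frame with `variable`, `r`, `p` (two-sided t reference),
#'   `n`.
#' @export
correlation_report <- function(score, companions, reference_ids = NULL) {
  if (inherits(score, "residualized_score"))
    score <- score$residual_standardized
  ids <- names(score) %||% as.character(seq_along(score))
  ref <- if (is.null(reference_ids)) seq_along(score)
         else match(reference_ids, ids)
  if (anyNA(ref)) stop("reference_ids not found among samples")
  companions <- as.data.frame(companions)
  do.call(rbind, lapply(names(companions), function(v) {
    x <- score[ref]; y <- companions[[v]][ref]
    okp <- stats::complete.cases(x, y)
    if (sum(okp) < 3L) stop("fewer than 3 paired observations for ", v)
    if (stats::sd(y[okp]) == 0) stop("zero-variance companion variable: ", v)
    ct <- stats::cor.test(x[okp], y[okp], method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(okp), stringsAsFactors = FALSE)
  }))
}
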