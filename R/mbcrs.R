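#' Fit a methylation-based breast cancer risk score (mBCRS)
#'
#' Derives a risk score from a candidate feature table (DNAm estimators plus
#' candidate CpGs) by observation-weighted elastic-net Cox regression with
#' k-fold cross-validated penalty selection. The score is the linear
#' combination of the selected features using the elastic-net coefficients
#' as weights. Training conventionally uses the age-balanced
#' inverse-probability selection weights of [training_selection_weights()]
#' on the training half of a case-cohort sample.
#'
#' @param features a [assemble_feature_table()] object, or a samples x
#'   features numeric matrix.
#' @param entry,exit,event per-sample survival coordinates (entry may be
#'   `NULL`). With `timescale = "study"` (the default for training) the model
#'   uses time on study, `(0, exit - entry]`; with `timescale = "age"` it
#'   uses left-truncated age intervals `(entry, exit]`.
#' @param weights per-sample observation weights (e.g. IPW); default 1.
#' @param alpha elastic-net mixing parameter (default 0.5, balancing L1 and
#'   L2).
#' @param nfolds cross-validation folds (default 10).
#' @param lambda_rule penalty selection rule: `"lambda_1se"` (default; the
#'   largest lambda within one fold standard error of the minimum CV
#'   deviance, favouring a sparse, stable component set) or `"lambda_min"`
#'   (deviance-minimizing).
#' @param timescale `"study"` or `"age"`.
#' @param seed integer seed for the fold draw.
#' @param ... passed to [cv_coxnet()] / [coxnet()].
#' @return An object of class `mbcrs`: coefficients on the original feature
#'   scale (`coefficients`, nonzero exactly on `selected_features`),
#'   `feature_class` of the selected features, the `cv` object, the chosen
#'   `lambda`, and training metadata (alpha, fold seed, standardization
#'   constants).
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n_cohort = 4000, seed = 7))
#' cc <- apply_case_cohort_sampling(sim$phenotypes, 0.05, seed = 7)
#' ph <- sim$phenotypes[match(cc$sample_id, sim$phenotypes$sample_id), ]
#' ft <- assemble_feature_table(subset(sim$matrix, samples = cc$sample_id),
#'                              sim$estimator_sets, sim$candidate_cpgs)
#' w <- training_selection_weights(ph$age_entry, cc$case)
#' fit <- mbcrs(ft, ph$age_entry, ph$age_exit, ph$event, weights = w,
#'              seed = 7)
#' print(fit)
#' head(predict(fit, ft))
#' }
#' @export
mbcrs <- function(features, entry = NULL, exit, event, weights = NULL,
                  alpha = 0.5, nfolds = 10L,
                  lambda_rule = c("lambda_1se", "lambda_min"),
                  timescale = c("study", "age"), seed = 1L, ...) {
  lambda_rule <- match.arg(lambda_rule)
  timescale <- match.arg(timescale)
  feature_class <- NULL
  if (inherits(features, "feature_table")) {
    feature_class <- features$feature_class
    features <- features$values
  }
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("features must have column names")
  n <- nrow(features)
  stopifnot(length(exit) == n, length(event) == n)
  if (timescale == "study") {
    start <- NULL
    stop_t <- if (is.null(entry)) exit else exit - entry
    if (any(stop_t <= 0)) stop("nonpositive follow-up time")
  } else {
    if (is.null(entry)) stop("age timescale requires entry ages")
    start <- entry
    stop_t <- exit
  }
  cv <- cv_coxnet(features, start, stop_t, event, weights, alpha = alpha,
                  nfolds = nfolds, seed = seed, ...)
  lam <- cv[[lambda_rule]]
  beta <- coef(cv$fit, lambda = lam)
  sel <- names(beta)[beta != 0]
  cls <- if (!is.null(feature_class)) feature_class[sel] else
    stats::setNames(rep(NA_character_, length(sel)), sel)
  structure(list(coefficients = beta[beta != 0],
                 selected_features = sel,
                 feature_class = cls,
                 lambda = lam, lambda_rule = lambda_rule,
                 alpha = alpha, nfolds = nfolds, seed = seed,
                 timescale = timescale,
                 center = cv$fit$center, scale = cv$fit$scale,
                 cv = cv, nobs = n, nevents = sum(event)),
            class = "mbcrs")
}

#' @export
print.mbcrs <- function(x, ...) {
  n_est <- sum(x$feature_class == "estimator", na.rm = TRUE)
  n_cpg <- sum(x$feature_class == "cpg", na.rm = TRUE)
  cat("Methylation-based risk score (weighted elastic-net Cox)\n")
  cat(sprintf("  %d training samples, %d events; alpha = %g, %d-fold CV (%s)\n",
              x$nobs, x$nevents, x$alpha, x$nfolds, x$lambda_rule))
  cat(sprintf("  selected %d feature(s)", length(x$selected_features)))
  if (n_est + n_cpg > 0)
    cat(sprintf(": %d DNAm estimator(s) + %d CpG(s)", n_est, n_cpg))
  cat(sprintf("; lambda = %.5g\n", x$lambda))
  invisible(x)
}

#' @export
summary.mbcrs <- function(object, ...) {
  tab <- data.frame(feature = object$selected_features,
                    class = unname(object$feature_class),
                    coefficient = unname(object$coefficients),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$coefficient)), ]
  rownames(tab) <- NULL
  out <- list(model = object, coefficients = tab)
  class(out) <- "summary.mbcrs"
  out
}

#' @export
print.summary.mbcrs <- function(x, ...) {
  print(x$model)
  cat("\nSelected components (by |coefficient|):\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.mbcrs <- function(object, ...) object$coefficients

#' Score samples with a fitted mBCRS model
#'
#' The score is the linear combination `sum_j coef_j feature_ij` on the
#' original feature scale; deterministic and transferable across datasets.
#'
#' @param object a fitted [mbcrs()] model.
#' @param features a `feature_table` or samples x features matrix containing
#'   every selected feature (missing ones raise an error naming them).
#' @param ... unused.
#' @return Named per-sample numeric score. An empty model scores every
#'   sample 0.
#' @export
predict.mbcrs <- function(object, features, ...) {
  if (inherits(features, "feature_table")) features <- features$values
  features <- as.matrix(features)
  sel <- object$selected_features
  if (length(sel) == 0L)
    return(stats::setNames(rep(0, nrow(features)), rownames(features)))
  missing <- setdiff(sel, colnames(features))
  if (length(missing))
    stop("selected feature(s) absent: ", paste(missing, collapse = ", "))
  drop(features[, sel, drop = FALSE] %*% object$coefficients)
}

#' Serialize an mBCRS model to JSON (and back)
#'
#' Stores the selected features, original-scale coefficients, feature
#' classes, and training metadata including the standardization constants,
#' so a stored model reproduces scores exactly on new data.
#'
#' @param model a fitted [mbcrs()] model.
#' @param path output JSON path.
#' @export
write_mbcrs <- function(model, path) {
  stopifnot(inherits(model, "mbcrs"))
  obj <- list(selected_features = model$selected_features,
              coefficients = as.list(model$coefficients),
              feature_class = as.list(model$feature_class),
              lambda = model$lambda, lambda_rule = model$lambda_rule,
              alpha = model$alpha, nfolds = model$nfolds,
              seed = model$seed, timescale = model$timescale,
              center = as.list(model$center), scale = as.list(model$scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mbcrs
#' @return [read_mbcrs()] returns an `mbcrs` model usable with
#'   [predict.mbcrs()].
#' @export
read_mbcrs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(obj$coefficients),
                 selected_features = obj$selected_features,
                 feature_class = unlist(obj$feature_class),
                 lambda = obj$lambda, lambda_rule = obj$lambda_rule,
                 alpha = obj$alpha, nfolds = obj$nfolds, seed = obj$seed,
                 timescale = obj$timescale,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 cv = NULL, nobs = NA_integer_, nevents = NA_integer_),
            class = "mbcrs")
}
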