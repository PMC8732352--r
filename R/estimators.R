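#' Linear DNAm estimator definition
#'
#' A DNAm estimator is an affine combination of probe beta values,
#' `transform(intercept + sum_j w_j beta_j)`, optionally passed through a
#' calibration transform. The package ships no published coefficient sets;
#' users load their own tables with [read_coefficient_set()] or generate
#' synthetic ones with [simulate_cohort()].
#'
#' @param name estimator name (used as the feature ID).
#' @param intercept numeric intercept.
#' @param weights named numeric vector, probe ID -> weight; at least one
#'   weight must be nonzero and probe IDs must be unique.
#' @param transform `"identity"`, `"age_calibration"` (the piecewise
#'   log/anti-log age transform used by first-generation epigenetic clocks,
#'   see [inverse_age_transform()]), or a monotone function of one argument.
#' @param output_units free-text units label.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(name, intercept, weights,
                            transform = "identity", output_units = "") {
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("weights must be uniquely named by probe ID")
  if (all(weights == 0)) stop("at least one weight must be nonzero")
  if (is.character(transform))
    transform <- match.arg(transform, c("identity", "age_calibration"))
  else if (!is.function(transform))
    stop("transform must be a name or a function")
  structure(list(name = name, intercept = as.numeric(intercept),
                 weights = weights, transform = transform,
                 output_units = output_units),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  tr <- if (is.function(x$transform)) "custom" else x$transform
  cat(sprintf("coefficient_set '%s': %d probes, intercept %.4g, transform %s\n",
              x$name, length(x$weights), x$intercept, tr))
  invisible(x)
}

#' Piecewise age calibration transform for first-generation clocks
#'
#' Maps the linear predictor of an age clock trained on
#' `log(age + 1) - log(adult_age + 1)` (for ages below `adult_age`) back to
#' years: `(1 + adult_age) * exp(x) - 1` for negative `x`, and
#' `(1 + adult_age) * x + adult_age` otherwise.
#'
#' @param x numeric linear predictor.
#' @param adult_age the knot age in years (default 20).
#' @return DNAm age in years.
#' @export
inverse_age_transform <- function(x, adult_age = 20) {
  ifelse(x < 0, (1 + adult_age) * exp(x) - 1, (1 + adult_age) * x + adult_age)
}

#' Compute a linear DNAm estimator for every sample
#'
#' @param matrix a [methylation_matrix()] (impute missing betas first; see
#'   [impute_missing_betas()]).
#' @param coeffs a [coefficient_set()].
#' @param missing_probes policy when coefficient probes are absent from the
#'   matrix: `"error"` stops, `"drop"` drops them with a warning. With zero
#'   overlapping probes the call always errors, listing the absent probes.
#' @return Named per-sample numeric vector; dropped probe IDs, if any, are in
#'   attribute `dropped_probes`.
#' @export
compute_linear_estimator <- function(matrix, coeffs,
                                     missing_probes = c("error", "drop")) {
  stopifnot(inherits(matrix, "methylation_matrix"),
            inherits(coeffs, "coefficient_set"))
  missing_probes <- match.arg(missing_probes)
  probes <- names(coeffs$weights)
  absent <- setdiff(probes, rownames(matrix$beta))
  if (length(absent) == length(probes))
    stop("no coefficient probes present in the matrix; missing: ",
         paste(utils::head(absent, 10L), collapse = ", "))
  if (length(absent)) {
    if (missing_probes == "error")
      stop("coefficient probes absent from matrix: ",
           paste(utils::head(absent, 10L), collapse = ", "))
    warning(sprintf("'%s': dropped %d absent probe(s)", coeffs$name,
                    length(absent)))
  }
  keep <- setdiff(probes, absent)
  v <- coeffs$intercept +
    drop(crossprod(matrix$beta[keep, , drop = FALSE], coeffs$weights[keep]))
  if (identical(coeffs$transform, "age_calibration"))
    v <- inverse_age_transform(v)
  else if (is.function(coeffs$transform))
    v <- coeffs$transform(v)
  names(v) <- colnames(matrix$beta)
  if (length(absent)) attr(v, "dropped_probes") <- absent
  v
}

#' Epigenetic age acceleration
#'
#' Residuals of DNAm age regressed on chronological age. The regression is
#' fit by least squares within a reference set (conventionally a
#' representative, cancer-free-at-sampling sample such as the random
#' subcohort) and applied to all samples, so reference residuals are
#' mean-zero and orthogonal to chronological age.
#'
#' @param dnam_age named per-sample DNAm age (years).
#' @param chron_age per-sample chronological age (years), same order.
#' @param reference_ids sample IDs defining the reference set (default: all).
#' @return Per-sample residuals in years, named as `dnam_age`.
#' @export
age_acceleration <- function(dnam_age, chron_age, reference_ids = NULL) {
  if (length(dnam_age) != length(chron_age))
    stop("dnam_age and chron_age lengths differ")
  if (!all(is.finite(dnam_age)) || !all(is.finite(chron_age)))
    stop("ages must be finite")
  ids <- names(dnam_age)
  ref <- if (is.null(reference_ids)) seq_along(dnam_age)
         else match(reference_ids, ids)
  if (anyNA(ref)) stop("reference_ids not found among samples")
  if (length(ref) < 3L) stop("need at least 3 reference samples")
  if (stats::sd(chron_age[ref]) == 0)
    stop("chronological age is constant in the reference set")
  fit <- stats::lm.fit(cbind(1, chron_age[ref]), dnam_age[ref])
  res <- dnam_age - (fit$coefficients[1L] + fit$coefficients[2L] * chron_age)
  stats::setNames(as.numeric(res), ids)
}

#' Assemble the candidate feature table
#'
#' One column per DNAm estimator and per candidate CpG (whose feature value
#' is the probe's beta), the input from which the risk score is derived.
#'
#' @param matrix a [methylation_matrix()].
#' @param estimator_sets list of [coefficient_set()] objects (may be empty).
#' @param candidate_cpgs character vector of candidate probe IDs.
#' @param missing_probes policy for candidate CpGs (and estimator probes)
#'   absent from the matrix: `"error"` or `"drop"` (drop warns and records
#'   the absent IDs).
#' @return An object of class `feature_table`: list with `values` (samples x
#'   features matrix), `feature_class` (named `"estimator"`/`"cpg"` vector)
#'   and `dropped` (absent candidate CpG IDs).
#' @export
assemble_feature_table <- function(matrix, estimator_sets, candidate_cpgs,
                                   missing_probes = c("error", "drop")) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  missing_probes <- match.arg(missing_probes)
  est_names <- vapply(estimator_sets, function(s) s$name, "")
  if (anyDuplicated(c(est_names, candidate_cpgs)))
    stop("duplicate feature names across estimators and candidate CpGs")
  absent <- setdiff(candidate_cpgs, rownames(matrix$beta))
  if (length(absent)) {
    if (missing_probes == "error")
      stop("candidate CpGs absent from matrix: ",
           paste(utils::head(absent, 10L), collapse = ", "))
    warning(sprintf("dropped %d absent candidate CpG(s)", length(absent)))
    candidate_cpgs <- setdiff(candidate_cpgs, absent)
  }
  n <- ncol(matrix$beta)
  est_vals <- if (length(estimator_sets))
    vapply(estimator_sets, function(s)
      as.numeric(compute_linear_estimator(matrix, s, missing_probes)),
      numeric(n))
  else matrix(numeric(0), nrow = n, ncol = 0L)
  colnames(est_vals) <- est_names
  cpg_vals <- t(matrix$beta[candidate_cpgs, , drop = FALSE])
  values <- cbind(est_vals, cpg_vals)
  rownames(values) <- colnames(matrix$beta)
  feature_class <- stats::setNames(
    c(rep("estimator", length(est_names)),
      rep("cpg", length(candidate_cpgs))),
    c(est_names, candidate_cpgs))
  structure(list(values = values, feature_class = feature_class,
                 dropped = absent),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d estimators, %d CpGs)\n",
              nrow(x$values), ncol(x$values),
              sum(x$feature_class == "estimator"),
              sum(x$feature_class == "cpg")))
  if (length(x$dropped))
    cat(sprintf("  %d candidate CpG(s) dropped as absent\n", length(x$dropped)))
  invisible(x)
}

#' Read and write coefficient-set files
#'
#' The on-disk format is a CSV with columns `probe_id`, `weight` plus a JSON
#' sidecar (same path with extension `.json`) carrying `name`, `intercept`,
#' `transform` and `output_units`.
#'
#' @param path path to the CSV file.
#' @return [read_coefficient_set()] returns a [coefficient_set()].
#' @export
read_coefficient_set <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  if (!all(c("probe_id", "weight") %in% names(tab)))
    stop("coefficient CSV needs columns probe_id, weight")
  side <- sub("\\.csv$", ".json", path, ignore.case = TRUE)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  coefficient_set(
    name = meta$name %||% sub("\\.csv$", "", basename(path), ignore.case = TRUE),
    intercept = meta$intercept %||% 0,
    weights = stats::setNames(tab$weight, tab$probe_id),
    transform = meta$transform %||% "identity",
    output_units = meta$output_units %||% "")
}

#' @rdname read_coefficient_set
#' @param coeffs a [coefficient_set()] to write.
#' @export
write_coefficient_set <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (is.function(coeffs$transform))
    stop("custom function transforms cannot be serialized")
  data.table::fwrite(data.frame(probe_id = names(coeffs$weights),
                                weight = as.numeric(coeffs$weights)), path)
  side <- sub("\\.csv$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(list(name = coeffs$name, intercept = coeffs$intercept,
                            transform = coeffs$transform,
                            output_units = coeffs$output_units),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
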