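#' Methylation beta-value matrix with per-sample QC metadata
#'
#' A light container for a probes x samples matrix of methylation beta values
#' (proportions in \[0, 1\], missing allowed) together with the per-sample
#' quality-control metadata used by [sample_qc()].
#'
#' @param beta numeric matrix, probes as rows and samples as columns, with
#'   row and column names set to probe and sample IDs.
#' @param sample_qc data.frame with columns `sample_id`, `mean_intensity`
#'   (mean bisulfite intensity, arbitrary units) and `low_quality_fraction`
#'   (proportion of probes failing any quality rule).
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, sample_qc) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe row names and sample column names")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  req <- c("sample_id", "mean_intensity", "low_quality_fraction")
  if (!all(req %in% names(sample_qc)))
    stop("sample_qc must have columns: ", paste(req, collapse = ", "))
  missing_qc <- setdiff(colnames(beta), sample_qc$sample_id)
  if (length(missing_qc))
    stop("sample_qc missing for sample(s): ",
         paste(utils::head(missing_qc, 5L), collapse = ", "))
  sample_qc <- sample_qc[match(colnames(beta), sample_qc$sample_id), ,
                         drop = FALSE]
  rownames(sample_qc) <- NULL
  structure(list(beta = beta, sample_qc = sample_qc),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d probes x %d samples (%d missing betas)\n",
              nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.methylation_matrix <- function(x) dim(x$beta)

#' Subset a methylation matrix by probes and/or samples
#' @param x a [methylation_matrix()].
#' @param probes,samples character vectors of IDs to keep (default: all).
#' @param ... unused.
#' @return A `methylation_matrix` restricted to the requested IDs.
#' @export
subset.methylation_matrix <- function(x, probes = NULL, samples = NULL, ...) {
  b <- x$beta
  if (!is.null(probes)) b <- b[probes, , drop = FALSE]
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  methylation_matrix(b, x$sample_qc[x$sample_qc$sample_id %in% colnames(b), ,
                                    drop = FALSE])
}

#' Sample-level quality control
#'
#' Excludes a sample when its mean bisulfite intensity is strictly below
#' `intensity_threshold` OR its fraction of low-quality probes is strictly
#' above `bad_probe_fraction`. Boundary samples (intensity exactly at the
#' threshold, bad-probe fraction exactly at the limit) are retained.
#'
#' @param matrix a [methylation_matrix()] with QC metadata for every sample.
#' @param intensity_threshold minimum acceptable mean intensity (default 4000).
#' @param bad_probe_fraction maximum acceptable low-quality-probe fraction
#'   (default 0.05).
#' @return A list with `pass` (character vector of passing sample IDs) and
#'   `report` (data.frame of excluded samples with logical reason columns
#'   `low_intensity` and `high_bad_probe`).
#' @export
sample_qc <- function(matrix, intensity_threshold = 4000,
                      bad_probe_fraction = 0.05) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  qc <- matrix$sample_qc
  if (anyNA(qc$mean_intensity) || anyNA(qc$low_quality_fraction)) {
    bad <- qc$sample_id[is.na(qc$mean_intensity) |
                        is.na(qc$low_quality_fraction)]
    stop("missing QC metadata for sample(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  low_int <- qc$mean_intensity < intensity_threshold
  high_bad <- qc$low_quality_fraction > bad_probe_fraction
  excl <- low_int | high_bad
  list(pass = qc$sample_id[!excl],
       report = data.frame(sample_id = qc$sample_id[excl],
                           low_intensity = low_int[excl],
                           high_bad_probe = high_bad[excl],
                           stringsAsFactors = FALSE))
}

#' Fraction of low-quality probes for one sample
#'
#' A probe is low-quality if its detection P-value exceeds 1e-6, it was
#' measured with fewer than 3 beads, or its value is an interquartile-range
#' outlier (see [iqr_outlier_flags()]). The fraction is the size of the union
#' of the three failure sets over the total probe count.
#'
#' @param detection_p per-probe detection P-values.
#' @param bead_count per-probe bead counts.
#' @param iqr_outlier per-probe logical outlier flags.
#' @param detection_p_max detection P threshold (default 1e-6, strict `>`).
#' @param min_beads minimum bead count (default 3, failure is strict `<`).
#' @return The low-quality fraction, a proportion in \[0, 1\].
#' @export
compute_low_quality_fraction <- function(detection_p, bead_count, iqr_outlier,
                                         detection_p_max = 1e-6,
                                         min_beads = 3L) {
  n <- length(detection_p)
  if (n == 0L) stop("empty probe set")
  stopifnot(length(bead_count) == n, length(iqr_outlier) == n)
  fail <- (detection_p > detection_p_max) | (bead_count < min_beads) |
    iqr_outlier
  mean(fail, na.rm = FALSE)
}

#' Flag interquartile-range outliers per probe across samples
#'
#' For each probe the reference distribution is its values across samples in
#' the batch; a value is flagged when it falls outside
#' \[Q1 - 3 IQR, Q3 + 3 IQR\].
#'
#' @param beta probes x samples matrix of beta values.
#' @param k IQR multiplier (default 3).
#' @return Logical matrix of the same shape; `NA` values are never flagged.
#' @export
iqr_outlier_flags <- function(beta, k = 3) {
  q <- t(apply(beta, 1L, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE))
  iqr <- q[, 2L] - q[, 1L]
  lo <- q[, 1L] - k * iqr
  hi <- q[, 2L] + k * iqr
  out <- (beta < lo) | (beta > hi)
  out[is.na(out)] <- FALSE
  out
}

#' Mean-impute missing beta values per probe
#'
#' @param matrix a [methylation_matrix()].
#' @return The matrix with missing betas replaced by the probe mean; the
#'   number of imputed entries is recorded in attribute `n_imputed` and
#'   reported with a message.
#' @export
impute_missing_betas <- function(matrix) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  b <- matrix$beta
  n_miss <- sum(is.na(b))
  if (n_miss > 0L) {
    means <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- means[idx[, 1L]]
    matrix$beta <- b
    message(sprintf("imputed %d missing beta values (probe means)", n_miss))
  }
  attr(matrix, "n_imputed") <- n_miss
  matrix
}

# ---- readers / writers -----------------------------------------------------

#' Read and write beta-value matrices
#'
#' Plain-text probe-major matrices: first column holds probe IDs, remaining
#' columns are samples, with a header row of sample IDs. The delimiter is
#' inferred from the file extension (`.tsv` = tab, otherwise comma).
#' [read_beta_matrix()] also accepts GEO series-matrix-style tables whose
#' first column is named `ID_REF` and which may carry `!`-prefixed comment
#' lines.
#'
#' @param path file path.
#' @param sample_qc optional QC metadata data.frame (see
#'   [methylation_matrix()]); if omitted, permissive placeholder metadata is
#'   attached so that QC excludes nothing.
#' @return [read_beta_matrix()] returns a `methylation_matrix`.
#' @export
read_beta_matrix <- function(path, sample_qc = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]  # GEO series-matrix comments
  dt <- data.table::fread(text = lines, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (names(dt)[1] %in% c("ID_REF", "id_ref"))
    names(dt)[1] <- "probe_id"
  probe_ids <- as.character(dt[[1L]])
  beta <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- probe_ids
  if (is.null(sample_qc))
    sample_qc <- data.frame(sample_id = colnames(beta),
                            mean_intensity = Inf,
                            low_quality_fraction = 0,
                            stringsAsFactors = FALSE)
  methylation_matrix(beta, sample_qc)
}

#' @rdname read_beta_matrix
#' @param matrix a [methylation_matrix()] to write.
#' @return [write_beta_matrix()] returns `path`, invisibly.
#' @export
write_beta_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dt <- data.table::data.table(probe_id = rownames(matrix$beta),
                               matrix$beta)
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Comma-separated tables with one row per woman. Required columns:
#' `sample_id`, `age_entry`, `age_exit`, `event`; any further columns
#' (subtype, risk factors, PRS, subcohort flag) pass through unchanged.
#'
#' @param path file path.
#' @return [read_phenotypes()] returns a data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- data.table::fread(path, data.table = FALSE)
  req <- c("sample_id", "age_entry", "age_exit", "event")
  miss <- setdiff(req, names(ph))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (any(ph$age_exit <= ph$age_entry))
    stop("age_exit must exceed age_entry for every woman")
  ph$sample_id <- as.character(ph$sample_id)
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path)
  invisible(path)
}
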