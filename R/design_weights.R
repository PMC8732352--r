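#' Split a case-cohort design into training and testing sets
#'
#' A simple random split at the woman level, reproducible under `seed`.
#'
#' @param design a `case_cohort_design` data.frame (see
#'   [apply_case_cohort_sampling()]) or any data.frame with one row per
#'   woman.
#' @param train_fraction proportion assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return The design with a `train_test` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(design, train_fraction = 0.70, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  set.seed(seed)
  n <- nrow(design)
  design$train_test <- ifelse(stats::runif(n) < train_fraction,
                              "train", "test")
  design
}

#' Age-balancing inverse-probability-of-selection weights
#'
#' In a case-cohort training sample cases are systematically older than
#' noncases at blood draw. These weights remove that imbalance: ages are
#' binned, cases keep weight 1, and noncases in bin *b* receive a weight
#' proportional to the case/noncase count ratio in *b*, rescaled so the
#' total noncase weight equals the noncase count. By construction the
#' weighted noncase age distribution over bins equals the case distribution
#' exactly. A case-containing bin with no noncases is widened locally by
#' merging it into its nearest neighboring bin (repeatedly, until every
#' case-containing bin has noncases), so the effective width adapts to the
#' sample size where the data are sparse while staying narrow elsewhere.
#' The default 1-year starting width keeps the residual within-bin age
#' gradient — and hence the weighted case/noncase mean-age gap — negligible
#' (well under 0.05 years at typical training sizes).
#'
#' @param ages per-woman age at blood draw (years).
#' @param case per-woman case indicator (0/1).
#' @param bin_width starting bin width in years (default 1, merged locally
#'   on sparsity).
#' @return Nonnegative per-woman weight vector (cases all 1); attribute
#'   `bins` holds the realized per-woman bin assignment.
#' @export
training_selection_weights <- function(ages, case, bin_width = 1) {
  stopifnot(length(ages) == length(case))
  case <- as.integer(case)
  if (!any(case == 1L) || !any(case == 0L))
    stop("need both cases and noncases")
  lo <- floor(min(ages))
  breaks <- seq(lo, max(ages) + bin_width, by = bin_width)
  grp <- findInterval(ages, breaks)  # ordered bin index per woman
  repeat {
    ids <- sort(unique(grp))
    n_case <- vapply(ids, function(g) sum(case == 1L & grp == g), 0L)
    n_non <- vapply(ids, function(g) sum(case == 0L & grp == g), 0L)
    off <- which(n_case > 0L & n_non == 0L)
    if (!length(off)) break
    if (length(ids) == 1L)
      stop("a case-containing age bin has no noncases even after merging")
    # merge the first offending bin into its nearest neighbor (the one
    # with more noncases on ties of distance)
    g <- off[1L]
    nb <- c(if (g > 1L) g - 1L, if (g < length(ids)) g + 1L)
    nb <- nb[order(abs(nb - g), -n_non[nb])][1L]
    grp[grp == ids[g]] <- ids[nb]
  }
  ratio_by_id <- n_case / n_non
  ratio_by_id[n_non == 0L] <- 0
  w <- ifelse(case == 1L, 1, ratio_by_id[match(grp, ids)])
  # within-bin linear tilt: align the weighted noncase mean age with the
  # case mean age inside each bin (keeps the bin totals, and hence the
  # bin-share balance, exactly; clipped to keep weights nonnegative)
  for (g in ids[n_case > 0L & n_non >= 2L]) {
    i_non <- which(case == 0L & grp == g)
    a <- ages[i_non]
    wb <- w[i_non]
    abar <- sum(wb * a) / sum(wb)
    s2 <- sum(wb * (a - abar)^2) / sum(wb)
    if (s2 <= 1e-10 * (1 + abar^2)) next  # effectively constant age in bin
    theta <- (mean(ages[case == 1L & grp == g]) - abar) / s2
    fac <- 1 + theta * (a - abar)
    if (any(fac < 0)) {
      shrink <- min(1 / abs(theta * (a - abar))[fac < 0])
      fac <- 1 + shrink * theta * (a - abar)
    }
    fac <- pmax(fac, 0)
    fac <- fac * sum(wb) / sum(wb * fac)  # preserve the bin total exactly
    w[i_non] <- wb * fac
  }
  non <- case == 0L
  tot_non <- sum(w[non])
  if (tot_non <= 0) stop("no noncase falls in any case-containing bin")
  w[non] <- w[non] * sum(non) / tot_non
  attr(w, "bins") <- grp
  w
}

#' Barlow weights for case-cohort Cox regression
#'
#' Expands a case-cohort design into counting-process risk intervals on the
#' age timescale with Barlow's pseudo-likelihood weights: subcohort members
#' represent the full cohort over their follow-up at weight
#' `1/sampling_fraction`; cases outside the subcohort enter the risk set
#' only just before their event, at weight 1; subcohort cases contribute
#' their pre-event person-time at `1/sampling_fraction` and their event
#' interval at weight 1.
#'
#' @param design data.frame with columns `sample_id`, `case`, `subcohort`,
#'   `age_entry`, `age_exit` (one row per woman).
#' @param sampling_fraction subcohort sampling fraction in (0, 1]; default
#'   taken from the design's `sampling_fraction` attribute.
#' @param eps age offset (years) defining the case event interval
#'   `(age_exit - eps, age_exit]` (default 0.001).
#' @return Long-format data.frame with one row per risk interval: columns
#'   `sample_id`, `start`, `stop`, `event`, `weight`.
#' @export
barlow_weights <- function(design, sampling_fraction = NULL, eps = 0.001) {
  if (is.null(sampling_fraction))
    sampling_fraction <- attr(design, "sampling_fraction")
  if (is.null(sampling_fraction))
    stop("sampling_fraction must be supplied or stored on the design")
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")
  req <- c("sample_id", "case", "subcohort", "age_entry", "age_exit")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(design$age_exit <= design$age_entry))
    stop("zero-length follow-up: age_exit must exceed age_entry")
  w_sub <- 1 / sampling_fraction
  rows <- vector("list", 3L)

  sub_non <- design$subcohort == 1L & design$case == 0L
  rows[[1L]] <- data.frame(sample_id = design$sample_id[sub_non],
                           start = design$age_entry[sub_non],
                           stop = design$age_exit[sub_non],
                           event = 0L, weight = w_sub)

  # a subcohort case with follow-up shorter than 2*eps gets only its event
  # interval (a zero-length pre-event interval would degenerate)
  sub_case <- design$subcohort == 1L & design$case == 1L &
    (design$age_exit - design$age_entry) > 2 * eps
  if (any(sub_case)) {
    pre_stop <- design$age_exit[sub_case] - eps
    rows[[2L]] <- rbind(
      data.frame(sample_id = design$sample_id[sub_case],
                 start = design$age_entry[sub_case],
                 stop = pre_stop, event = 0L, weight = w_sub),
      data.frame(sample_id = design$sample_id[sub_case],
                 start = pre_stop, stop = design$age_exit[sub_case],
                 event = 1L, weight = 1))
  }
  short_case <- design$subcohort == 1L & design$case == 1L & !sub_case
  if (any(short_case))
    rows[[2L]] <- rbind(rows[[2L]], data.frame(
      sample_id = design$sample_id[short_case],
      start = design$age_entry[short_case],
      stop = design$age_exit[short_case], event = 1L, weight = 1))

  out_case <- design$subcohort == 0L & design$case == 1L
  if (any(out_case)) {
    ent <- pmax(design$age_exit[out_case] - eps,
                design$age_entry[out_case])
    rows[[3L]] <- data.frame(sample_id = design$sample_id[out_case],
                             start = ent,
                             stop = design$age_exit[out_case],
                             event = 1L, weight = 1)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out <- out[order(out$sample_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
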