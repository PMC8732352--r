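#' Configuration for a synthetic methylation case-cohort study
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate a large prospective cohort of women aged 35-74 sampled
#' with a ~3% random subcohort, an administratively censored mean follow-up
#' of about 5.2 years, and a sparse set of hazard-associated methylation
#' features.
#'
#' @param n_cohort number of women in the full cohort.
#' @param n_probes number of CpG probes on the array.
#' @param n_causal_probes number of candidate CpGs that carry hazard signal.
#' @param n_estimators number of synthetic DNAm estimators (each a weighted
#'   linear combination of a dedicated probe panel).
#' @param n_causal_estimators number of estimators whose values carry hazard
#'   signal.
#' @param effect_per_sd log hazard ratio per standard deviation of each causal
#'   feature; scalar (recycled) or vector of length
#'   `n_causal_probes + n_causal_estimators`.
#' @param baseline_hazard baseline event rate in events per person-year at the
#'   reference age (55 years).
#' @param age_slope log-hazard increase per year of age in the baseline hazard
#'   (makes cases systematically older than noncases at entry).
#' @param age_range entry-age range in years, length-2 numeric.
#' @param admin_followup mean administrative follow-up in years; individual
#'   follow-up is drawn uniformly around this mean.
#' @param followup_halfwidth half-width of the uniform follow-up distribution
#'   (years); the default gives SD near 2.6 years.
#' @param subcohort_fraction proportion of the cohort sampled into the random
#'   subcohort, in (0, 1].
#' @param n_candidate_cpgs size of the candidate CpG panel (causal probes are
#'   drawn from this panel).
#' @param panel_size number of probes per synthetic estimator panel.
#' @param rf_effects named numeric vector of log hazard ratios for the
#'   questionnaire risk-factor stand-ins; names must be a subset of
#'   `c("bmi", "menopause", "parity", "alcohol", "activity", "smoking")`.
#' @param prs_effect log hazard ratio per SD of the polygenic risk score.
#' @param seed integer seed; all randomness in [simulate_cohort()] flows from
#'   it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_cohort = 20000L,
                       n_probes = 500L,
                       n_causal_probes = 19L,
                       n_estimators = 36L,
                       n_causal_estimators = 5L,
                       effect_per_sd = log(1.4),
                       baseline_hazard = 0.001,
                       age_slope = 0.07,
                       age_range = c(35, 74),
                       admin_followup = 5.2,
                       followup_halfwidth = 4.5,
                       subcohort_fraction = 0.03,
                       n_candidate_cpgs = 100L,
                       panel_size = 10L,
                       rf_effects = c(bmi = 0.02, alcohol = 0.03,
                                      activity = -0.004),
                       prs_effect = log(1.5),
                       seed = 1L) {
  cfg <- list(
    n_cohort = as.integer(n_cohort), n_probes = as.integer(n_probes),
    n_causal_probes = as.integer(n_causal_probes),
    n_estimators = as.integer(n_estimators),
    n_causal_estimators = as.integer(n_causal_estimators),
    effect_per_sd = as.numeric(effect_per_sd),
    baseline_hazard = baseline_hazard, age_slope = age_slope,
    age_range = as.numeric(age_range), admin_followup = admin_followup,
    followup_halfwidth = followup_halfwidth,
    subcohort_fraction = subcohort_fraction,
    n_candidate_cpgs = as.integer(n_candidate_cpgs),
    panel_size = as.integer(panel_size),
    rf_effects = rf_effects, prs_effect = prs_effect,
    seed = as.integer(seed))

  for (nm in c("n_cohort", "n_probes", "panel_size"))
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a positive count", nm))
  for (nm in c("n_estimators", "n_candidate_cpgs", "n_causal_probes",
               "n_causal_estimators"))
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop(sprintf("'%s' must be a nonnegative count", nm))
  if (cfg$n_causal_probes > cfg$n_candidate_cpgs)
    stop("n_causal_probes must not exceed n_candidate_cpgs")
  if (cfg$n_causal_estimators > cfg$n_estimators)
    stop("n_causal_estimators must not exceed n_estimators")
  if (cfg$n_candidate_cpgs + cfg$n_estimators * cfg$panel_size > cfg$n_probes)
    stop("n_probes too small for the candidate panel plus estimator panels")
  if (!all(is.finite(cfg$effect_per_sd)) ||
      !all(is.finite(cfg$rf_effects)) || !is.finite(cfg$prs_effect))
    stop("effect sizes must be finite")
  n_causal <- cfg$n_causal_probes + cfg$n_causal_estimators
  if (!(length(cfg$effect_per_sd) %in% c(1L, max(n_causal, 1L))))
    stop("effect_per_sd must be scalar or one value per causal feature")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    stop("age_range must be an increasing pair of ages")
  if (cfg$subcohort_fraction <= 0 || cfg$subcohort_fraction > 1)
    stop("subcohort_fraction must be in (0, 1]")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$admin_followup <= cfg$followup_halfwidth)
    stop("admin_followup must exceed followup_halfwidth")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic case-cohort configuration\n")
  cat(sprintf("  cohort: %d women, entry ages %g-%g, subcohort fraction %g\n",
              x$n_cohort, x$age_range[1], x$age_range[2],
              x$subcohort_fraction))
  cat(sprintf("  array: %d probes; %d candidate CpGs (%d causal)\n",
              x$n_probes, x$n_candidate_cpgs, x$n_causal_probes))
  cat(sprintf("  estimators: %d (%d causal), panels of %d probes\n",
              x$n_estimators, x$n_causal_estimators, x$panel_size))
  cat(sprintf("  hazard: %g /py at age 55, age slope %g/yr, follow-up ~%g yr\n",
              x$baseline_hazard, x$age_slope, x$admin_followup))
  invisible(x)
}

logit <- function(p) log(p / (1 - p))

#' Simulate a methylation case-cohort study with known ground truth
#'
#' Generates a full cohort of women with beta-distributed methylation values,
#' synthetic DNAm estimators built as linear combinations of dedicated probe
#' panels, questionnaire risk-factor stand-ins, a polygenic risk score, and
#' age-timescale survival with left truncation at entry. The hazard is
#' `baseline_hazard * exp(age_slope * (age - 55)) * exp(lp)` where `lp` is
#' the true linear predictor: the dot product of the standardized causal
#' features (candidate CpG betas and estimator values), risk factors and PRS
#' with their true log hazard ratios. Events are generated by inverting the
#' cumulative hazard over `(entry, entry + follow-up]`.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{matrix}{a [methylation_matrix()]: beta values (probes x samples)
#'     with clean per-sample QC metadata.}
#'   \item{phenotypes}{data.frame with `sample_id`, `age_entry`, `age_exit`,
#'     `event`, `subtype`, `er_status`, risk factors, and `prs`.}
#'   \item{truth}{list with `causal_probe_ids`, `causal_estimator_ids`,
#'     `true_effects` (named log-HRs for every hazard term), and
#'     `true_linear_predictor` (per-woman log relative hazard).}
#'   \item{estimator_sets}{list of [coefficient_set()] objects defining the
#'     synthetic estimators.}
#'   \item{candidate_cpgs}{the candidate CpG probe IDs.}
#' }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cohort
  p <- config$n_probes

  sample_ids <- sprintf("S%05d", seq_len(n))
  probe_ids <- sprintf("cg%08d", seq_len(p))

  # probe layout: candidate CpG panel first, then disjoint estimator panels
  candidate_cpgs <- probe_ids[seq_len(config$n_candidate_cpgs)]
  causal_probes <- if (config$n_causal_probes > 0L)
    candidate_cpgs[seq_len(config$n_causal_probes)] else character(0)
  panel_start <- config$n_candidate_cpgs
  panels <- lapply(seq_len(config$n_estimators), function(k) {
    probe_ids[panel_start + (k - 1L) * config$panel_size +
              seq_len(config$panel_size)]
  })

  # beta values: per-probe mean Uniform(0.1, 0.9), logit-normal sample noise
  mu <- stats::runif(p, 0.1, 0.9)
  noise_sd <- stats::runif(p, 0.25, 0.6)
  beta <- matrix(stats::rnorm(p * n, rep(logit(mu), n), rep(noise_sd, n)),
                 nrow = p, ncol = n,
                 dimnames = list(probe_ids, sample_ids))
  beta <- stats::plogis(beta)

  # synthetic estimators: exact linear combinations of their panels
  estimator_ids <- sprintf("dnam_est_%02d", seq_len(config$n_estimators))
  estimator_sets <- vector("list", config$n_estimators)
  est_values <- matrix(0, n, config$n_estimators,
                       dimnames = list(sample_ids, estimator_ids))
  for (k in seq_len(config$n_estimators)) {
    w <- stats::rnorm(config$panel_size, 0, 2)
    icpt <- stats::rnorm(1, 40, 10)
    estimator_sets[[k]] <- coefficient_set(
      name = estimator_ids[k], intercept = icpt,
      weights = stats::setNames(w, panels[[k]]))
    est_values[, k] <- icpt + drop(crossprod(beta[panels[[k]], , drop = FALSE], w))
  }
  causal_estimators <- if (config$n_causal_estimators > 0L)
    estimator_ids[seq_len(config$n_causal_estimators)] else character(0)

  # risk-factor stand-ins (independent; simplified continuous/binary)
  rf <- data.frame(
    bmi = stats::rnorm(n, 27.6, 6),
    menopause = stats::rbinom(n, 1, 0.7),
    parity = stats::rpois(n, 1.9),
    alcohol = stats::rexp(n, 1 / 3.1),
    activity = pmax(stats::rnorm(n, 50.8, 31), 0),
    smoking = stats::rexp(n, 1 / 6),
    age_menarche = round(stats::rnorm(n, 12.6, 1.4), 1),
    age_first_birth = round(stats::rnorm(n, 24.9, 5), 1),
    famhx_n = 1L + stats::rbinom(n, 2, 0.05),
    education = sample(1:3, n, replace = TRUE, prob = c(0.16, 0.59, 0.25)))
  prs <- stats::rnorm(n)

  # true linear predictor: exact dot product of standardized causal features
  zstd <- function(v) (v - mean(v)) / stats::sd(v)
  n_causal <- config$n_causal_probes + config$n_causal_estimators
  eff <- rep_len(config$effect_per_sd, max(n_causal, 1L))
  lp <- numeric(n)
  true_effects <- numeric(0)
  if (config$n_causal_probes > 0L) {
    e_p <- eff[seq_len(config$n_causal_probes)]
    zb <- apply(beta[causal_probes, , drop = FALSE], 1L, zstd)  # n x k
    lp <- lp + drop(zb %*% e_p)
    true_effects <- c(true_effects, stats::setNames(e_p, causal_probes))
  }
  if (config$n_causal_estimators > 0L) {
    e_e <- eff[config$n_causal_probes + seq_len(config$n_causal_estimators)]
    ze <- apply(est_values[, causal_estimators, drop = FALSE], 2L, zstd)
    lp <- lp + drop(ze %*% e_e)
    true_effects <- c(true_effects, stats::setNames(e_e, causal_estimators))
  }
  rf_eff <- config$rf_effects
  if (length(rf_eff)) {
    bad <- setdiff(names(rf_eff), names(rf))
    if (length(bad)) stop("unknown rf_effects names: ",
                          paste(bad, collapse = ", "))
    for (nm in names(rf_eff)) lp <- lp + rf_eff[[nm]] * rf[[nm]]
    # center risk-factor contribution so lp stays a relative log hazard
    lp <- lp - sum(vapply(names(rf_eff),
                          function(nm) rf_eff[[nm]] * mean(rf[[nm]]), 0))
    true_effects <- c(true_effects, rf_eff)
  }
  lp <- lp + config$prs_effect * prs
  true_effects <- c(true_effects, prs = config$prs_effect)

  # age-timescale survival: h(a) = h0 exp(slope (a - 55)) exp(lp),
  # entry ~ Uniform(age_range), administrative censoring at entry + followup
  age_entry <- stats::runif(n, config$age_range[1], config$age_range[2])
  fu <- stats::runif(n, config$admin_followup - config$followup_halfwidth,
                     config$admin_followup + config$followup_halfwidth)
  rate_mult <- config$baseline_hazard * exp(lp)
  k <- config$age_slope
  ee <- stats::rexp(n)  # target cumulative hazard
  if (abs(k) < 1e-12) {
    t_event <- ee / rate_mult
  } else {
    # H(t) = rate_mult * exp(k (entry - 55)) * (exp(k t) - 1) / k
    a0 <- rate_mult * exp(k * (age_entry - 55)) / k
    arg <- 1 + ee / a0
    t_event <- ifelse(arg > 0, log(arg) / k, Inf)
  }
  event <- as.integer(t_event <= fu & is.finite(t_event))
  age_exit <- age_entry + ifelse(event == 1L, t_event, fu)

  subtype <- rep("none", n)
  er_status <- rep("unknown", n)
  idx_case <- which(event == 1L)
  if (length(idx_case)) {
    inv <- stats::rbinom(length(idx_case), 1, 0.79) == 1L
    subtype[idx_case] <- ifelse(inv, "invasive", "DCIS")
    er_status[idx_case][inv] <-
      ifelse(stats::rbinom(sum(inv), 1, 0.8) == 1L, "positive", "negative")
  }

  phenotypes <- data.frame(sample_id = sample_ids,
                           age_entry = age_entry, age_exit = age_exit,
                           event = event, subtype = subtype,
                           er_status = er_status,
                           rf, prs = prs, stringsAsFactors = FALSE)

  qc <- data.frame(sample_id = sample_ids,
                   mean_intensity = stats::rnorm(n, 9000, 1200),
                   low_quality_fraction = stats::rbeta(n, 1, 80))
  qc$mean_intensity <- pmax(qc$mean_intensity, 4500)
  qc$low_quality_fraction <- pmin(qc$low_quality_fraction, 0.045)

  list(matrix = methylation_matrix(beta, qc),
       phenotypes = phenotypes,
       truth = list(causal_probe_ids = causal_probes,
                    causal_estimator_ids = causal_estimators,
                    true_effects = true_effects,
                    true_linear_predictor = stats::setNames(lp, sample_ids)),
       estimator_sets = estimator_sets,
       candidate_cpgs = candidate_cpgs)
}

#' Draw a case-cohort sample: all cases plus a random subcohort
#'
#' Every woman with an event is included as a case; an independent simple
#' random sample of the whole cohort (drawn without regard to case status)
#' forms the random subcohort, so subcohort members who become cases are
#' flagged as both.
#'
#' @param phenotypes phenotype data.frame with `sample_id` and `event`.
#' @param fraction subcohort sampling fraction in (0, 1].
#' @param seed integer seed for the subcohort draw.
#' @return A `case_cohort_design` data.frame with columns `sample_id`, `case`,
#'   `subcohort`, restricted to the sampled women, plus attributes
#'   `sampling_fraction` and `n_cohort`.
#' @export
apply_case_cohort_sampling <- function(phenotypes, fraction, seed = 1L) {
  if (nrow(phenotypes) == 0L) stop("empty cohort")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(seed)
  n <- nrow(phenotypes)
  in_sub <- stats::rbinom(n, 1L, fraction)
  keep <- phenotypes$event == 1L | in_sub == 1L
  design <- data.frame(sample_id = phenotypes$sample_id[keep],
                       case = as.integer(phenotypes$event[keep] == 1L),
                       subcohort = in_sub[keep],
                       stringsAsFactors = FALSE)
  attr(design, "sampling_fraction") <- fraction
  attr(design, "n_cohort") <- n
  class(design) <- c("case_cohort_design", "data.frame")
  design
}

#' Plant sample-level QC failures into a methylation matrix
#'
#' Test fixture helper: marks exactly `n_low_intensity` randomly chosen
#' samples with mean bisulfite intensity below 4000, and `n_high_badprobe`
#' further samples with a low-quality-probe fraction above 5%. All other
#' samples are reset to pass both rules.
#'
#' @param matrix a [methylation_matrix()].
#' @param n_low_intensity number of samples to fail the intensity rule.
#' @param n_high_badprobe number of samples to fail the bad-probe rule.
#' @param seed integer seed for choosing which samples fail.
#' @return The matrix with modified `sample_qc` metadata.
#' @export
plant_qc_failures <- function(matrix, n_low_intensity, n_high_badprobe,
                              seed = 1L) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  n <- ncol(matrix$beta)
  if (n_low_intensity + n_high_badprobe > n)
    stop("requested failures exceed the sample count")
  set.seed(seed)
  qc <- matrix$sample_qc
  qc$mean_intensity <- pmax(qc$mean_intensity, 4500)
  qc$low_quality_fraction <- pmin(qc$low_quality_fraction, 0.045)
  pick <- sample.int(n, n_low_intensity + n_high_badprobe)
  low <- pick[seq_len(n_low_intensity)]
  bad <- pick[n_low_intensity + seq_len(n_high_badprobe)]
  qc$mean_intensity[low] <- stats::runif(n_low_intensity, 1500, 3999)
  qc$low_quality_fraction[bad] <- stats::runif(n_high_badprobe, 0.051, 0.3)
  matrix$sample_qc <- qc
  matrix
}
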