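#' Configuration of the synthetic Cq generator
#'
#' Describes a plasma miRNA qPCR panel run: 84 miRNA assays (3 of them
#' references, one the red-blood-cell hemolysis marker), 4 spike-in
#' channels at roughly 100-fold concentration steps, and two groups of 10
#' samples. Case effects are injected on the Cq scale — a true log2
#' fold change of `delta` in expression is a `-delta`-cycle shift — so the
#' normalization identity holds exactly in the noiseless limit. Each sample
#' also carries a global Cq offset (input-amount variation) that reference
#' normalization must cancel, and everything above the limit-of-detection
#' ceiling is censored to "not detected".
#'
#' @param n_case,n_control group sizes (default 10 / 10)
#' @param n_assays total miRNA assays on the panel, references and
#'   hemolysis marker included (default 84; spike-ins come on top)
#' @param reference_ids,reference_baseline reference assay ids and their
#'   baseline Cq
#' @param rbc_marker_id,rbc_baseline the RBC hemolysis marker and its
#'   baseline Cq (abundant, hence low)
#' @param target_baseline_mean,target_baseline_sd baseline Cq distribution
#'   of the remaining target assays (Normal, cycles)
#' @param effects named numeric vector `assay_id -> true log2 fold change`
#'   in cases; assays not named have no effect
#' @param noise_sd technical noise per well (cycles)
#' @param sample_effect_sd sd of the per-sample global Cq offset (cycles)
#' @param lod_ceiling Cq above this is censored to missing (strict `>`)
#' @param hemolysis_samples sample ids contaminated with red-cell content
#' @param hemolysis_shift cycles subtracted from the RBC marker in
#'   contaminated samples
#' @param spike_baseline named baseline Cq of the spike-in channels
#'   (defaults step by ~6.64 cycles = 100-fold concentration)
#' @param confounder_strength SD shift of age/NIHSS in cases (0 emulates an
#'   already-matched cohort)
#' @param seed default RNG seed for [simulate_cq_dataset()]
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(
    n_case = 10, n_control = 10, n_assays = 84,
    reference_ids = c("hsa-miR-30c-5p", "hsa-miR-103a-3p", "hsa-miR-23a-3p"),
    reference_baseline = c(30, 31, 29),
    rbc_marker_id = "hsa-miR-451a",
    rbc_baseline = 24,
    target_baseline_mean = 28, target_baseline_sd = 3,
    effects = numeric(0),
    noise_sd = 0.5,
    sample_effect_sd = 0.5,
    lod_ceiling = 37,
    hemolysis_samples = character(0),
    hemolysis_shift = 4,
    spike_baseline = c(UniSp2 = 19.5, UniSp4 = 26.1,
                       UniSp5 = 32.7, UniSp6 = 18.8),
    confounder_strength = 0,
    seed = 123) {
  stopifnot(n_case >= 1, n_control >= 1,
            length(reference_ids) == length(reference_baseline),
            n_assays >= length(reference_ids) + 1,
            noise_sd >= 0, sample_effect_sd >= 0,
            lod_ceiling > 0, lod_ceiling <= 45)
  if (length(effects) && is.null(names(effects)))
    stop("`effects` must be named by assay id")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a Cq dataset with known truth
#'
#' Generates `Cq(s, a) = baseline_a - case(s) * delta_a - sample_effect(s)
#' + noise`, injects hemolysis into the configured samples, then applies
#' limit-of-detection censoring. Deterministic given the seed.
#'
#' @param config a [synthetic_config()]
#' @param seed RNG seed (default: `config$seed`)
#' @return list with `cq` (a [cq_matrix()] including spike-in channels),
#'   `metadata` (sample data frame with group and matching covariates) and
#'   `truth` (per-assay true log2 effects, per-sample hemolysis status,
#'   censored fractions, seed)
#' @export
simulate_cq_dataset <- function(config = synthetic_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)

  n <- config$n_case + config$n_control
  sample_id <- c(sprintf("HT-%02d", seq_len(config$n_case)),
                 sprintf("C-%02d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))

  n_targets <- config$n_assays - length(config$reference_ids) - 1
  target_ids <- sprintf("synth-mir-%03d", seq_len(n_targets))
  assay_id <- c(config$reference_ids, config$rbc_marker_id, target_ids,
                names(config$spike_baseline))
  baseline <- c(config$reference_baseline, config$rbc_baseline,
                stats::rnorm(n_targets, config$target_baseline_mean,
                             config$target_baseline_sd),
                unname(config$spike_baseline))
  names(baseline) <- assay_id

  delta <- stats::setNames(rep(0, length(assay_id)), assay_id)
  unknown <- setdiff(names(config$effects), assay_id)
  if (length(unknown))
    stop("effect(s) for unknown assay(s): ", paste(unknown, collapse = ", "))
  delta[names(config$effects)] <- config$effects

  sample_effect <- stats::rnorm(n, 0, config$sample_effect_sd)
  cq <- matrix(baseline, nrow = n, ncol = length(assay_id), byrow = TRUE,
               dimnames = list(sample_id, assay_id))
  cq <- cq -
    outer(as.numeric(group == "case"), delta) -
    matrix(sample_effect, n, length(assay_id)) +
    matrix(stats::rnorm(n * length(assay_id), 0, config$noise_sd),
           n, length(assay_id))
  cq <- pmin(pmax(cq, 0.01), 45)

  roles <- stats::setNames(rep("target", length(assay_id)), assay_id)
  roles[config$reference_ids] <- "reference"
  roles[config$rbc_marker_id] <- "hemolysis_marker"
  roles[names(config$spike_baseline)] <- "spike_in"
  x <- cq_matrix(cq, roles)

  if (length(config$hemolysis_samples))
    x <- inject_hemolysis(x, config$hemolysis_samples,
                          config$hemolysis_shift,
                          rbc_assays = config$rbc_marker_id)
  x <- apply_lod_censoring(x, config$lod_ceiling)

  # matching covariates; confounder_strength > 0 emulates an unmatched
  # cohort in which cases are older and more severe
  age <- round(stats::rnorm(n, 75, 8) +
                 config$confounder_strength * 8 * (group == "case"))
  nihss <- pmax(0, round(stats::rnorm(n, 6, 3) +
                           config$confounder_strength * 3 *
                           (group == "case")))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ocsp <- sample(c("PACS", "TACS"), n, replace = TRUE, prob = c(0.7, 0.3))
  metadata <- data.frame(sample_id = sample_id, group = group,
                         age = age, sex = sex, nihss = nihss, ocsp = ocsp,
                         excluded = FALSE, exclusion_reason = "",
                         stringsAsFactors = FALSE)

  hemo <- stats::setNames(sample_id %in% config$hemolysis_samples, sample_id)
  truth <- list(
    effects = delta,
    hemolysis = hemo,
    group = stats::setNames(group, sample_id),
    censored_fraction = colMeans(is.na(x$cq)),
    seed = seed
  )
  list(cq = x, metadata = metadata, truth = truth)
}

#' Inject hemolysis contamination
#'
#' Red-cell lysis floods the plasma with miR-451a, so contamination lowers
#' the RBC-marker Cq. Subtracts `shift` cycles from the listed assays
#' (default: the marker only) in the listed samples.
#'
#' @param x a `cq_matrix`
#' @param samples sample ids to contaminate (unknown id is an error)
#' @param shift cycles to subtract
#' @param rbc_assays assays affected (default `"hsa-miR-451a"`)
#' @return the modified `cq_matrix`
#' @export
inject_hemolysis <- function(x, samples, shift,
                             rbc_assays = "hsa-miR-451a") {
  unknown <- setdiff(samples, sample_ids(x))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  unknown_a <- setdiff(rbc_assays, assay_ids(x))
  if (length(unknown_a))
    stop("unknown assay id(s): ", paste(unknown_a, collapse = ", "))
  cq <- x$cq
  cq[samples, rbc_assays] <- cq[samples, rbc_assays] - shift
  cq_matrix(cq, x$assay_role)
}

#' Limit-of-detection censoring
#'
#' Template too dilute to amplify before the cycle ceiling is reported as
#' "not detected": every Cq strictly above `ceiling` becomes missing.
#'
#' @param x a `cq_matrix`
#' @param ceiling LOD ceiling in cycles, within (0, 45]
#' @return the censored `cq_matrix`
#' @export
apply_lod_censoring <- function(x, ceiling = 37) {
  stopifnot(ceiling > 0, ceiling <= 45)
  cq <- x$cq
  cq[!is.na(cq) & cq > ceiling] <- NA_real_
  cq_matrix(cq, x$assay_role)
}

#' Simulate a confounded, unmatched cohort for matching experiments
#'
#' Draws a control pool and assigns case status through a logistic model on
#' age and NIHSS, so that cases are systematically older and more severe —
#' the situation propensity matching is meant to repair.
#'
#' @param n_case target number of cases
#' @param n_pool total cohort size to draw from
#' @param confounder_strength logistic coefficient scale; 0 means no
#'   confounding
#' @param seed RNG seed
#' @return data frame with `sample_id`, `group`, and covariates `age`,
#'   `sex`, `nihss`, `ocsp`
#' @export
simulate_matching_cohort <- function(n_case = 10, n_pool = 50,
                                     confounder_strength = 1, seed = 1) {
  stopifnot(n_pool > n_case)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  age <- round(stats::rnorm(n_pool, 75, 8))
  nihss <- pmax(0, round(stats::rnorm(n_pool, 6, 3)))
  sex <- sample(c("F", "M"), n_pool, replace = TRUE)
  ocsp <- sample(c("PACS", "TACS"), n_pool, replace = TRUE,
                 prob = c(0.7, 0.3))
  lin <- confounder_strength * (scale(age)[, 1] + scale(nihss)[, 1])
  prob <- stats::plogis(lin)
  # weighted draw of exactly n_case cases
  case_idx <- sample.int(n_pool, n_case, prob = prob + 1e-6)
  group <- ifelse(seq_len(n_pool) %in% case_idx, "case", "control")
  data.frame(sample_id = sprintf("P-%03d", seq_len(n_pool)),
             group = group, age = age, sex = sex, nihss = nihss,
             ocsp = ocsp, stringsAsFactors = FALSE)
}
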