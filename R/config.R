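#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with the defaults used throughout:
#' the three plasma reference miRNAs, the miR-23a/miR-451a hemolysis pair
#' with its dCq > 7 rule, a strict >50% assay-missingness filter, a
#' 10%-trimmed permutation Yuen-Welch test with B = 1000 relabelings at seed
#' 123, significance level 0.10 and dysregulation fold-change bounds
#' 0.67 / 1.5.
#'
#' @param reference_assays assay ids whose per-sample mean Cq anchors
#'   normalization
#' @param hemolysis_pair length-2 character: the blood-constant marker and
#'   the red-blood-cell marker, in that order; dCq = Cq(constant) - Cq(rbc)
#' @param hemolysis_threshold flag a sample as hemolyzed when dCq exceeds
#'   this many cycles (strict)
#' @param missingness_threshold exclude a target assay when its missing
#'   fraction exceeds this (strict)
#' @param trim trim proportion gamma of the Yuen-Welch test, in [0, 0.5)
#' @param n_permutations number of label permutations B
#' @param rng_seed root seed for all randomness in testing
#' @param alpha significance level applied to raw permutation p-values
#' @param fc_low,fc_high fold-change bounds: down below `fc_low`, up above
#'   `fc_high` (both strict)
#' @param spike_window warn when a sample's spike-in Cq deviates from the
#'   cohort median by more than this many cycles
#' @param outlier_rule rule for flagging reference-signal outlier samples:
#'   `"robust_z"` (median/MAD z-score) or `"gap"` (gap to next-highest mean)
#' @param outlier_z_cutoff robust z cutoff for `outlier_rule = "robust_z"`
#' @param outlier_gap cycle gap for `outlier_rule = "gap"`
#' @param geometric_group_means use geometric instead of arithmetic group
#'   means when computing fold changes
#' @return a list of class `analysis_config`
#' @export
analysis_config <- function(
    reference_assays = c("hsa-miR-30c-5p", "hsa-miR-103a-3p", "hsa-miR-23a-3p"),
    hemolysis_pair = c("hsa-miR-23a-3p", "hsa-miR-451a"),
    hemolysis_threshold = 7,
    missingness_threshold = 0.5,
    trim = 0.10,
    n_permutations = 1000,
    rng_seed = 123,
    alpha = 0.10,
    fc_low = 0.67,
    fc_high = 1.5,
    spike_window = 2,
    outlier_rule = c("robust_z", "gap"),
    outlier_z_cutoff = 3.5,
    outlier_gap = 3,
    geometric_group_means = FALSE) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(
    length(reference_assays) >= 1,
    length(hemolysis_pair) == 2,
    is.numeric(hemolysis_threshold), length(hemolysis_threshold) == 1,
    missingness_threshold >= 0, missingness_threshold <= 1,
    is.numeric(n_permutations), n_permutations >= 1
  )
  if (!(trim >= 0 && trim < 0.5))
    stop("`trim` must lie in [0, 0.5)")
  if (!(fc_low > 0 && fc_low < 1 && fc_high > 1))
    stop("need 0 < fc_low < 1 < fc_high")
  if (!(alpha > 0 && alpha < 1))
    stop("`alpha` must lie in (0, 1)")
  structure(list(
    reference_assays = reference_assays,
    hemolysis_pair = hemolysis_pair,
    hemolysis_threshold = hemolysis_threshold,
    missingness_threshold = missingness_threshold,
    trim = trim,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    alpha = alpha,
    fc_low = fc_low,
    fc_high = fc_high,
    spike_window = spike_window,
    outlier_rule = outlier_rule,
    outlier_z_cutoff = outlier_z_cutoff,
    outlier_gap = outlier_gap,
    geometric_group_means = geometric_group_means
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields mirror [analysis_config()] one-for-one; absent fields keep their
#' defaults, unknown fields are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return an `analysis_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json, got: ", path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
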