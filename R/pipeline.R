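#' Run the full Cq differential-expression pipeline
#'
#' One call from raw Cq table to classified differential table, in the
#' fixed stage order: spike-in QC, hemolysis dCq, reference-outlier sample
#' detection, manual exclusions, assay missingness filter, reference
#' normalization, per-assay permutation Yuen-Welch testing with
#' Benjamini-Hochberg adjustment, dysregulation classification. Hemolyzed
#' samples are flagged but retained unless `drop_hemolyzed = TRUE` (mild
#' hemolysis is near-unavoidable in clinical plasma and the flag is
#' propagated to the outputs either way). All randomness flows from
#' `config$rng_seed`, so a rerun with identical inputs is byte-identical.
#'
#' @param cq a [cq_matrix()] or a path readable by [read_cq_table()]
#' @param metadata a metadata data frame or a path readable by
#'   [read_sample_metadata()]
#' @param config an [analysis_config()]
#' @param manual_exclusions data frame `(id, kind, reason)` of exclusions
#'   decided outside the pipeline (e.g. non-specific amplification), or
#'   `NULL`
#' @param drop_hemolyzed exclude hemolysis-flagged samples instead of
#'   only flagging them
#' @param annotation assay-role annotation, used when `cq` is a path
#' @param out_dir when given, result files are written there via
#'   [write_results()]
#' @return list with `diff_table`, `qc_report`, `normalized`, `manifest`,
#'   `spike_report`
#' @export
run_pipeline <- function(cq, metadata, config = analysis_config(),
                         manual_exclusions = NULL, drop_hemolyzed = FALSE,
                         annotation = NULL, out_dir = NULL) {
  if (is.character(cq)) cq <- read_cq_table(cq, annotation = annotation)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  stopifnot(inherits(cq, "cq_matrix"))
  validate_samples(cq, metadata)

  sample_log <- data.frame(sample_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  drop_sample <- function(ids, reason) {
    ids <- setdiff(ids, sample_log$sample_id)
    if (length(ids))
      sample_log <<- rbind(sample_log,
                           data.frame(sample_id = ids, reason = reason,
                                      stringsAsFactors = FALSE))
  }
  drop_sample(metadata$sample_id[metadata$excluded],
              "pre_excluded_in_metadata")

  x <- subset_cq(cq, samples = intersect(sample_ids(cq),
                                         metadata$sample_id))
  n_samples_in <- nrow(x$cq)
  targets_in <- assays_with_role(x, "target")

  spikes <- withCallingHandlers(
    spike_in_report(x, window = config$spike_window),
    warning = function(w) invokeRestart("muffleWarning"))
  hemo <- suppressWarnings(
    compute_hemolysis_dcq(x, pair = config$hemolysis_pair,
                          threshold = config$hemolysis_threshold))
  if (drop_hemolyzed)
    drop_sample(hemo$sample_id[!is.na(hemo$hemolysis_flag) &
                                 hemo$hemolysis_flag], "hemolysis")

  outliers <- suppressWarnings(detect_reference_outlier_samples(
    x, reference_assays = config$reference_assays,
    rule = config$outlier_rule, z_cutoff = config$outlier_z_cutoff,
    gap = config$outlier_gap))
  drop_sample(outliers$sample_id[outliers$flag], "reference_outlier")

  manual <- apply_manual_exclusions(x, manual_exclusions)
  x <- manual$cq
  drop_sample(manual$log$id[manual$log$kind == "sample"], "manual")

  keep_samples <- setdiff(sample_ids(x), sample_log$sample_id)
  if (length(keep_samples) == 0) stop("all samples excluded by QC")
  x <- subset_cq(x, samples = keep_samples)

  miss <- apply_missingness_filter(x, config$missingness_threshold)
  keep_assays <- c(setdiff(assay_ids(x), miss$excluded))
  x <- subset_cq(x, assays = keep_assays)

  norm <- normalize_expression(x, config$reference_assays)
  groups <- stats::setNames(metadata$group, metadata$sample_id)[keep_samples]
  diff <- run_differential(norm, groups, config)

  qc <- build_qc_report(hemolysis = hemo, spikes = spikes,
                        ref_outliers = outliers,
                        assay_table = miss$table,
                        manual_log = manual$log)

  counts <- list(
    samples_in = n_samples_in,
    samples_excluded = nrow(sample_log),
    samples_analyzed = length(keep_samples),
    target_assays_in = length(targets_in),
    assays_excluded_missingness = length(miss$excluded),
    assays_excluded_manual = sum(manual$log$kind == "assay"),
    assays_tested = sum(diff$note == ""),
    assays_not_evaluable = sum(diff$note != ""),
    n_up = sum(diff$class == "up"),
    n_down = sum(diff$class == "down"),
    n_not_significant = sum(diff$class == "not_significant")
  )
  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    n_permutations = config$n_permutations,
    counts = counts,
    excluded_samples = sample_log,
    excluded_assays = qc$assays[qc$assays$excluded,
                                c("assay_id", "reason"), drop = FALSE],
    hemolysis_flagged = hemo$sample_id[!is.na(hemo$hemolysis_flag) &
                                         hemo$hemolysis_flag],
    package_version = as.character(utils::packageVersion("cqdiff"))
  )
  if (!is.null(out_dir))
    write_results(diff, qc, out_dir, manifest = manifest)
  list(diff_table = diff, qc_report = qc, normalized = norm,
       manifest = manifest, spike_report = spikes)
}
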