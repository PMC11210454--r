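#' Hemolysis indicator dCq per sample
#'
#' Plasma hemolysis releases red-blood-cell miR-451a, lowering its Cq while
#' the blood-constant miR-23a stays put, so
#' `dCq = Cq(constant) - Cq(rbc)` grows with contamination. A sample is
#' flagged when dCq strictly exceeds the threshold (7 cycles by the usual
#' vendor rule).
#'
#' @param x a `cq_matrix`
#' @param pair length-2 character: ids of the constant marker and the RBC
#'   marker, in that order
#' @param threshold flag when `dcq > threshold` (strict)
#' @return data frame with one row per sample: `sample_id`, `cq_constant`,
#'   `cq_rbc`, `dcq`, `hemolysis_flag`. A sample missing either marker gets
#'   `NA` dcq and flag, with a warning.
#' @export
compute_hemolysis_dcq <- function(x, pair = c("hsa-miR-23a-3p",
                                              "hsa-miR-451a"),
                                  threshold = 7) {
  stopifnot(length(pair) == 2)
  absent <- setdiff(pair, assay_ids(x))
  if (length(absent))
    stop("hemolysis marker assay(s) not in matrix: ",
         paste(absent, collapse = ", "))
  const_cq <- x$cq[, pair[1]]
  rbc_cq <- x$cq[, pair[2]]
  dcq <- const_cq - rbc_cq
  if (anyNA(dcq))
    warning("hemolysis dCq undefined for sample(s) with a missing marker: ",
            paste(sample_ids(x)[is.na(dcq)], collapse = ", "))
  data.frame(
    sample_id = sample_ids(x),
    cq_constant = unname(const_cq),
    cq_rbc = unname(rbc_cq),
    dcq = unname(dcq),
    hemolysis_flag = unname(dcq > threshold),
    stringsAsFactors = FALSE
  )
}

#' Spike-in QC summary
#'
#' Spike-ins (UniSp2/4/5/6) are added at known concentrations to monitor RNA
#' isolation and cDNA-synthesis efficiency; their Cq should be tight across
#' samples. For each annotated spike-in this reports every sample's Cq, the
#' cohort min/max/median, and warns when a sample deviates from the cohort
#' median by more than `window` cycles.
#'
#' @param x a `cq_matrix`
#' @param spike_ids spike-in assay ids; default: assays with role `spike_in`
#' @param window warn beyond this absolute deviation from the median
#'   (cycles)
#' @return data frame `(sample_id, assay_id, cq, median_cq, deviation,
#'   warn)`; zero rows (with a warning) when no spike-ins are annotated.
#'   The per-spike min/max summary is attached as attribute `"summary"`.
#' @export
spike_in_report <- function(x, spike_ids = NULL, window = 2) {
  spike_ids <- spike_ids %||% assays_with_role(x, "spike_in")
  spike_ids <- intersect(spike_ids, assay_ids(x))
  empty <- data.frame(sample_id = character(0), assay_id = character(0),
                      cq = numeric(0), median_cq = numeric(0),
                      deviation = numeric(0), warn = logical(0),
                      stringsAsFactors = FALSE)
  if (length(spike_ids) == 0) {
    warning("no spike-in assays annotated; spike QC skipped")
    attr(empty, "summary") <- data.frame(assay_id = character(0),
                                         min_cq = numeric(0),
                                         max_cq = numeric(0))
    return(empty)
  }
  rows <- lapply(spike_ids, function(a) {
    cq <- x$cq[, a]
    med <- stats::median(cq, na.rm = TRUE)
    dev <- cq - med
    data.frame(sample_id = sample_ids(x), assay_id = a,
               cq = unname(cq), median_cq = med, deviation = unname(dev),
               warn = unname(abs(dev) > window),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, lapply(spike_ids, function(a) {
    cq <- x$cq[, a]
    data.frame(assay_id = a,
               min_cq = suppressWarnings(min(cq, na.rm = TRUE)),
               max_cq = suppressWarnings(max(cq, na.rm = TRUE)))
  }))
  out
}

#' Flag samples whose reference signal is an outlier
#'
#' Computes each sample's arithmetic-mean reference Cq and flags outliers: a
#' sample with globally degraded template shows a mean reference Cq cycles
#' above the cohort. Two explicit rules are provided, because "looked like
#' an outlier" is not reproducible: `robust_z` flags samples whose
#' median/MAD z-score exceeds `z_cutoff`; `gap` flags a sample whose mean
#' exceeds the highest remaining mean by more than `gap` cycles. A sample
#' with no detectable reference at all is always flagged
#' (`no_reference_signal`).
#'
#' @param x a `cq_matrix`
#' @param reference_assays reference assay ids; default: role `reference`
#' @param rule `"robust_z"` or `"gap"`
#' @param z_cutoff robust z threshold (default 3.5)
#' @param gap cycle gap threshold (default 3)
#' @return data frame `(sample_id, mean_reference_cq, n_ref, stat, flag,
#'   reason)`
#' @export
detect_reference_outlier_samples <- function(x, reference_assays = NULL,
                                             rule = c("robust_z", "gap"),
                                             z_cutoff = 3.5, gap = 3) {
  rule <- match.arg(rule)
  reference_assays <- reference_assays %||% assays_with_role(x, "reference")
  absent <- setdiff(reference_assays, assay_ids(x))
  if (length(absent))
    stop("reference assay(s) not in matrix: ", paste(absent, collapse = ", "))
  if (length(reference_assays) == 0)
    stop("no reference assays given or annotated")
  ref <- x$cq[, reference_assays, drop = FALSE]
  n_ref <- rowSums(!is.na(ref))
  means <- rowMeans(ref, na.rm = TRUE)
  means[n_ref == 0] <- NA_real_

  out <- data.frame(sample_id = sample_ids(x),
                    mean_reference_cq = unname(means),
                    n_ref = unname(n_ref),
                    stat = NA_real_, flag = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  out$flag[out$n_ref == 0] <- TRUE
  out$reason[out$n_ref == 0] <- "no_reference_signal"

  usable <- !is.na(out$mean_reference_cq)
  if (sum(usable) < 2) {
    if (sum(usable) == 1)
      warning("only one sample with reference signal; outlier rule not applied")
    return(out)
  }
  m <- out$mean_reference_cq[usable]
  if (rule == "robust_z") {
    med <- stats::median(m)
    s <- stats::mad(m)  # 1.4826 * median absolute deviation
    z <- if (s > 0) (m - med) / s else ifelse(m == med, 0, Inf * sign(m - med))
    out$stat[usable] <- z
    hit <- abs(z) > z_cutoff
  } else {
    # gap rule: does this sample sit > `gap` cycles above every other sample?
    hi <- vapply(seq_along(m), function(i) m[i] - max(m[-i]), numeric(1))
    out$stat[usable] <- hi
    hit <- hi > gap
  }
  out$flag[usable] <- out$flag[usable] | hit
  out$reason[usable][hit] <- paste0("reference_outlier_", rule)
  out
}

#' Assay-level missingness filter
#'
#' A target assay is excluded when it is missing ("not detected") in
#' strictly more than `threshold` of the currently retained samples —
#' i.e. "more than 50%" keeps an assay missing in exactly half. Reference,
#' hemolysis-marker and spike-in assays are exempt from exclusion but their
#' missing fractions are still reported.
#'
#' @param x a `cq_matrix` already restricted to retained samples
#' @param threshold missing-fraction cutoff (strict `>`)
#' @return list with `retained` and `excluded` (character vectors of target
#'   assay ids) and `table`, a per-assay data frame
#'   `(assay_id, role, missing_fraction, excluded, reason)`
#' @export
apply_missingness_filter <- function(x, threshold = 0.5) {
  frac <- colMeans(is.na(x$cq))
  role <- x$assay_role[colnames(x$cq)]
  is_target <- role == "target"
  excluded <- is_target & frac > threshold
  tab <- data.frame(
    assay_id = colnames(x$cq),
    role = unname(role),
    missing_fraction = unname(frac),
    excluded = unname(excluded),
    reason = ifelse(excluded, "missingness", ""),
    stringsAsFactors = FALSE
  )
  list(retained = colnames(x$cq)[is_target & !excluded],
       excluded = colnames(x$cq)[excluded],
       table = tab)
}

#' Apply manual assay/sample exclusions
#'
#' Exclusions the pipeline cannot recompute — e.g. an assay dropped for
#' non-specific amplification seen on the instrument — enter as an explicit
#' list and are logged. Duplicated entries collapse to a single log line.
#'
#' @param x a `cq_matrix`
#' @param exclusions data frame with columns `id`, `kind` (`"assay"` or
#'   `"sample"`) and `reason`; `NULL` or zero rows leaves `x` unchanged
#' @return list with `cq` (the reduced matrix) and `log` (the deduplicated
#'   exclusion records actually applied)
#' @export
apply_manual_exclusions <- function(x, exclusions) {
  log0 <- data.frame(id = character(0), kind = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  if (is.null(exclusions) || nrow(exclusions) == 0)
    return(list(cq = x, log = log0))
  stopifnot(all(c("id", "kind", "reason") %in% names(exclusions)))
  if (!all(exclusions$kind %in% c("assay", "sample")))
    stop("exclusion kind must be `assay` or `sample`")
  ex <- unique(exclusions[, c("id", "kind", "reason")])
  ex <- ex[!duplicated(ex[, c("id", "kind")]), , drop = FALSE]
  bad_a <- setdiff(ex$id[ex$kind == "assay"], assay_ids(x))
  bad_s <- setdiff(ex$id[ex$kind == "sample"], sample_ids(x))
  if (length(bad_a) || length(bad_s))
    stop("unknown id(s) in exclusion list: ",
         paste(c(bad_a, bad_s), collapse = ", "))
  keep_a <- setdiff(assay_ids(x), ex$id[ex$kind == "assay"])
  keep_s <- setdiff(sample_ids(x), ex$id[ex$kind == "sample"])
  list(cq = subset_cq(x, samples = keep_s, assays = keep_a), log = ex)
}

#' Assemble the QC report
#'
#' Joins the per-sample gates (hemolysis dCq, spike-in warnings, reference
#' outlier verdicts) and the per-assay gates (missingness, manual
#' exclusions) into one object that [write_results()] serializes.
#'
#' @param hemolysis output of [compute_hemolysis_dcq()]
#' @param spikes output of [spike_in_report()]
#' @param ref_outliers output of [detect_reference_outlier_samples()]
#' @param assay_table `table` element of [apply_missingness_filter()]
#' @param manual_log `log` element of [apply_manual_exclusions()]
#' @return object of class `qc_report` with elements `samples` and `assays`
#' @export
build_qc_report <- function(hemolysis, spikes = NULL, ref_outliers = NULL,
                            assay_table = NULL, manual_log = NULL) {
  samples <- hemolysis
  if (!is.null(ref_outliers)) {
    ro <- ref_outliers[, c("sample_id", "mean_reference_cq", "n_ref",
                           "flag", "reason")]
    names(ro)[4:5] <- c("reference_outlier_flag", "reference_outlier_reason")
    samples <- merge(samples, ro, by = "sample_id", all = TRUE, sort = FALSE)
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    warned <- stats::aggregate(warn ~ sample_id, data = spikes, FUN = any)
    names(warned)[2] <- "spike_warn"
    samples <- merge(samples, warned, by = "sample_id", all = TRUE,
                     sort = FALSE)
  }
  assays <- assay_table %||%
    data.frame(assay_id = character(0), role = character(0),
               missing_fraction = numeric(0), excluded = logical(0),
               reason = character(0), stringsAsFactors = FALSE)
  if (!is.null(manual_log) && nrow(manual_log) > 0) {
    man_a <- manual_log[manual_log$kind == "assay", , drop = FALSE]
    add <- !(man_a$id %in% assays$assay_id)
    if (any(add)) {
      assays <- rbind(assays, data.frame(
        assay_id = man_a$id[add], role = "target",
        missing_fraction = NA_real_, excluded = TRUE,
        reason = man_a$reason[add], stringsAsFactors = FALSE))
    }
    hit <- match(man_a$id, assays$assay_id)
    ok <- !is.na(hit)
    assays$excluded[hit[ok]] <- TRUE
    assays$reason[hit[ok]] <- man_a$reason[ok]
  }
  structure(list(samples = samples, assays = assays), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples, %d assays\n",
              nrow(x$samples), nrow(x$assays)))
  if ("hemolysis_flag" %in% names(x$samples))
    cat(sprintf("  hemolysis-flagged samples: %d\n",
                sum(x$samples$hemolysis_flag, na.rm = TRUE)))
  if (nrow(x$assays))
    cat(sprintf("  excluded assays: %d\n", sum(x$assays$excluded)))
  invisible(x)
}
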