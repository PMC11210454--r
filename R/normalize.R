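#' Per-sample mean reference Cq
#'
#' Arithmetic mean of the sample's present reference-assay Cq values; the
#' number of references actually used is recorded (partial reference dropout
#' does not fail the sample, it just narrows the mean). A sample with no
#' detectable reference is an error — it should have been removed by QC.
#'
#' @param x a `cq_matrix`
#' @param reference_assays reference assay ids; default: role `reference`
#' @return named numeric vector of mean reference Cq per sample, with the
#'   per-sample reference count attached as attribute `"n_ref"`
#' @export
mean_reference_cq <- function(x, reference_assays = NULL) {
  reference_assays <- reference_assays %||% assays_with_role(x, "reference")
  absent <- setdiff(reference_assays, assay_ids(x))
  if (length(absent))
    stop("reference assay(s) not in matrix: ", paste(absent, collapse = ", "))
  if (length(reference_assays) == 0)
    stop("no reference assays given or annotated")
  ref <- x$cq[, reference_assays, drop = FALSE]
  n_ref <- rowSums(!is.na(ref))
  if (any(n_ref == 0))
    stop("no reference signal for sample(s): ",
         paste(sample_ids(x)[n_ref == 0], collapse = ", "),
         " (exclude them before normalization)")
  m <- rowMeans(ref, na.rm = TRUE)
  attr(m, "n_ref") <- stats::setNames(n_ref, sample_ids(x))
  m
}

#' Reference-normalized relative expression
#'
#' Converts Cq to relative expression against the reference mean:
#' `expr(s, a) = 2^-(Cq(s, a) - meanRefCq(s))`. A target at its sample's
#' mean reference Cq has expression exactly 1; each cycle below the
#' reference mean doubles it. Because the reference mean is per-sample, any
#' global per-sample Cq offset (pipetting, input amount) cancels exactly.
#' Missing Cq stays missing. Only target assays are carried into the result;
#' references, hemolysis markers and spike-ins have done their job by now.
#'
#' @param x a `cq_matrix` restricted to QC-retained samples/assays
#' @param reference_assays reference assay ids; default: role `reference`
#' @return numeric matrix (samples x target assays) of positive relative
#'   expression values, with attributes `"reference_assays"` and `"n_ref"`
#' @export
normalize_expression <- function(x, reference_assays = NULL) {
  reference_assays <- reference_assays %||% assays_with_role(x, "reference")
  ref_mean <- mean_reference_cq(x, reference_assays)
  targets <- assays_with_role(x, "target")
  expr <- 2^(-(x$cq[, targets, drop = FALSE] - ref_mean))
  attr(expr, "reference_assays") <- reference_assays
  attr(expr, "n_ref") <- attr(ref_mean, "n_ref")
  expr
}

#' Per-assay fold change between case and control
#'
#' Fold change is the quotient of the mean normalized expression in cases
#' over controls, computed per assay on complete cases (samples missing the
#' assay are dropped from that assay's means, not imputed). An assay with a
#' group entirely missing is marked not evaluable.
#'
#' @param norm matrix from [normalize_expression()] (samples x assays)
#' @param groups named character vector `sample_id -> "case"/"control"`, or
#'   a metadata data frame with `sample_id` and `group` columns
#' @param geometric use geometric instead of arithmetic group means
#' @return data frame `(assay_id, n_case, n_control, mean_case,
#'   mean_control, fc, log2_fc, evaluable)`
#' @export
fold_change <- function(norm, groups, geometric = FALSE) {
  groups <- .as_group_vector(groups, rownames(norm))
  case_rows <- names(groups)[groups == "case"]
  ctrl_rows <- names(groups)[groups == "control"]
  if (length(case_rows) == 0 || length(ctrl_rows) == 0)
    stop("need at least one case and one control sample")
  gmean <- function(v) exp(mean(log(v)))
  agg <- function(v) if (geometric) gmean(v) else mean(v)
  rows <- lapply(colnames(norm), function(a) {
    vc <- norm[case_rows, a]
    vc <- vc[!is.na(vc)]
    vn <- norm[ctrl_rows, a]
    vn <- vn[!is.na(vn)]
    evaluable <- length(vc) >= 1 && length(vn) >= 1
    mc <- if (length(vc)) agg(vc) else NA_real_
    mn <- if (length(vn)) agg(vn) else NA_real_
    fc <- if (evaluable) mc / mn else NA_real_
    data.frame(assay_id = a, n_case = length(vc), n_control = length(vn),
               mean_case = mc, mean_control = mn,
               fc = fc, log2_fc = log2(fc), evaluable = evaluable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.as_group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  }
  if (is.null(names(groups)))
    stop("`groups` must be named by sample id")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be `case` or `control`")
  known <- intersect(sample_ids, names(groups))
  if (length(known) == 0) stop("no overlap between groups and samples")
  groups[known]
}
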