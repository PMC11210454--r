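#' Construct a Cq matrix
#'
#' The central container of the package: a samples-by-assays matrix of qPCR
#' quantification-cycle (Cq) values together with a role annotation for every
#' assay. Lower Cq means more abundant template; `NA` encodes "not detected"
#' (the instrument never crossed threshold), which is distinct from any
#' numeric value.
#'
#' @param cq numeric matrix, samples as rows and assays as columns, with
#'   unique non-empty dimnames. `NA` marks undetected wells.
#' @param assay_role named character vector mapping assay ids to one of
#'   `"target"`, `"reference"`, `"hemolysis_marker"`, `"spike_in"`. Assays not
#'   named here default to `"target"`.
#' @return an object of class `cq_matrix`: a list with elements `cq`
#'   (the validated matrix) and `assay_role` (a complete role map).
#' @examples
#' m <- matrix(c(24, 25, 30, NA), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("miR-a", "miR-b")))
#' x <- cq_matrix(m)
#' assay_ids(x)
#' @export
cq_matrix <- function(cq, assay_role = NULL) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("`cq` must be a numeric matrix (samples x assays)")
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("`cq` must have sample ids as rownames and assay ids as colnames")
  if (anyDuplicated(rownames(cq)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(cq)[duplicated(rownames(cq))]), collapse = ", "))
  if (anyDuplicated(colnames(cq)))
    stop("duplicate assay ids: ",
         paste(unique(colnames(cq)[duplicated(colnames(cq))]), collapse = ", "))
  bad <- which(!is.na(cq) & (cq <= 0 | cq > 45), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "Cq value outside (0, 45] at sample '%s', assay '%s': %g",
      rownames(cq)[bad[1, 1]], colnames(cq)[bad[1, 2]],
      cq[bad[1, 1], bad[1, 2]]))
  }
  roles <- rep("target", ncol(cq))
  names(roles) <- colnames(cq)
  if (!is.null(assay_role)) {
    if (is.null(names(assay_role)))
      stop("`assay_role` must be a named character vector")
    valid <- c("target", "reference", "hemolysis_marker", "spike_in")
    if (!all(assay_role %in% valid))
      stop("assay roles must be one of: ", paste(valid, collapse = ", "))
    known <- intersect(names(assay_role), colnames(cq))
    roles[known] <- assay_role[known]
  }
  structure(list(cq = cq, assay_role = roles), class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("<cq_matrix> %d samples x %d assays\n",
              nrow(x$cq), ncol(x$cq)))
  tab <- table(factor(x$assay_role,
                      c("target", "reference", "hemolysis_marker", "spike_in")))
  cat("  roles:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing: %d / %d wells (%.1f%%)\n",
              sum(is.na(x$cq)), length(x$cq),
              100 * mean(is.na(x$cq))))
  invisible(x)
}

#' @rdname cq_matrix
#' @param x a `cq_matrix`
#' @export
sample_ids <- function(x) rownames(x$cq)

#' @rdname cq_matrix
#' @export
assay_ids <- function(x) colnames(x$cq)

#' Assays carrying a given role
#' @param x a `cq_matrix`
#' @param role one of `"target"`, `"reference"`, `"hemolysis_marker"`,
#'   `"spike_in"`
#' @return character vector of assay ids
#' @export
assays_with_role <- function(x, role) {
  names(x$assay_role)[x$assay_role == role]
}

#' Subset a Cq matrix by sample and/or assay ids
#'
#' Unknown ids are an error; role annotation is carried along.
#'
#' @param x a `cq_matrix`
#' @param samples,assays character vectors of ids to keep (default: all)
#' @return a `cq_matrix`
#' @export
subset_cq <- function(x, samples = sample_ids(x), assays = assay_ids(x)) {
  miss_s <- setdiff(samples, sample_ids(x))
  if (length(miss_s)) stop("unknown sample id(s): ", paste(miss_s, collapse = ", "))
  miss_a <- setdiff(assays, assay_ids(x))
  if (length(miss_a)) stop("unknown assay id(s): ", paste(miss_a, collapse = ", "))
  cq_matrix(x$cq[samples, assays, drop = FALSE], x$assay_role[assays])
}
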