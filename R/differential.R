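#' Per-assay differential testing and dysregulation classification
#'
#' For every assay of the normalized matrix: fold change on complete cases,
#' a permutation Yuen-Welch test, then a Benjamini-Hochberg adjustment
#' across all tested assays. Classification into up/down uses the *raw*
#' permutation p-value against `config$alpha` together with the fold-change
#' bounds; the adjusted p-value is reported alongside. Assays with fewer
#' than two complete cases in either group are not testable and appear with
#' class `excluded`.
#'
#' Per-assay permutation seeds are spawned once from `config$rng_seed` in
#' assay order, so every assay's p-value is reproducible and independent of
#' how many other assays are tested first (given the same retained assay
#' list).
#'
#' @param norm matrix from [normalize_expression()]
#' @param groups named `sample_id -> "case"/"control"` vector or a metadata
#'   data frame
#' @param config an [analysis_config()]
#' @return data frame of class `diff_table`: one row per assay with
#'   `assay_id`, `n_case`, `n_control`, `fc`, `log2_fc`, `t_yuen`, `p_perm`,
#'   `p_adj`, `class`, `note`
#' @export
run_differential <- function(norm, groups, config = analysis_config()) {
  groups <- .as_group_vector(groups, rownames(norm))
  fc_tab <- fold_change(norm, groups,
                        geometric = isTRUE(config$geometric_group_means))
  n_assay <- ncol(norm)
  if (n_assay == 0) {
    warning("no assays to test")
    return(.empty_diff_table())
  }
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$rng_seed)
  assay_seeds <- sample.int(.Machine$integer.max, n_assay)

  case_rows <- names(groups)[groups == "case"]
  ctrl_rows <- names(groups)[groups == "control"]
  t_yuen <- p_perm <- rep(NA_real_, n_assay)
  note <- rep("", n_assay)
  for (j in seq_len(n_assay)) {
    vx <- norm[case_rows, j]
    vx <- vx[!is.na(vx)]
    vy <- norm[ctrl_rows, j]
    vy <- vy[!is.na(vy)]
    if (length(vx) < 2 || length(vy) < 2) {
      note[j] <- "insufficient_complete_cases"
      next
    }
    res <- permutation_yuen_test(vx, vy, trim = config$trim,
                                 B = config$n_permutations,
                                 seed = assay_seeds[j])
    t_yuen[j] <- res$t_obs
    p_perm[j] <- res$p_perm
  }
  p_adj <- bh_adjust(p_perm)
  cls <- classify_dysregulation(fc_tab$fc, p_perm,
                                alpha = config$alpha,
                                fc_low = config$fc_low,
                                fc_high = config$fc_high)
  cls[note != ""] <- "excluded"
  out <- data.frame(
    assay_id = fc_tab$assay_id,
    n_case = fc_tab$n_case, n_control = fc_tab$n_control,
    fc = fc_tab$fc, log2_fc = fc_tab$log2_fc,
    t_yuen = t_yuen, p_perm = p_perm, p_adj = p_adj,
    class = cls, note = note,
    stringsAsFactors = FALSE
  )
  class(out) <- c("diff_table", "data.frame")
  out
}

.empty_diff_table <- function() {
  out <- data.frame(assay_id = character(0), n_case = integer(0),
                    n_control = integer(0), fc = numeric(0),
                    log2_fc = numeric(0), t_yuen = numeric(0),
                    p_perm = numeric(0), p_adj = numeric(0),
                    class = character(0), note = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Classify assays as up- or down-regulated
#'
#' `down` when `fc < fc_low` and `p < alpha`; `up` when `fc > fc_high` and
#' `p < alpha`; otherwise `not_significant`. All three boundaries are
#' strict. Undefined inputs yield `excluded`.
#'
#' @param fc fold-change vector (case over control)
#' @param p raw permutation p-values
#' @param alpha significance level (default 0.10)
#' @param fc_low,fc_high fold-change bounds (defaults 0.67 and 1.5)
#' @return character vector in
#'   `{"up", "down", "not_significant", "excluded"}`
#' @export
classify_dysregulation <- function(fc, p, alpha = 0.10,
                                   fc_low = 0.67, fc_high = 1.5) {
  stopifnot(length(fc) == length(p))
  out <- rep("not_significant", length(fc))
  out[!is.na(fc) & !is.na(p) & fc < fc_low & p < alpha] <- "down"
  out[!is.na(fc) & !is.na(p) & fc > fc_high & p < alpha] <- "up"
  out[is.na(fc) | is.na(p)] <- "excluded"
  out
}

#' Volcano-plot coordinates
#'
#' Returns `(log2_fc, -log10 p)` per testable assay plus the guide lines at
#' the significance level and the two fold-change bounds. Rows classified
#' `excluded` produce no coordinates.
#'
#' @param diff a `diff_table`
#' @param alpha,fc_low,fc_high thresholds drawn as guide lines
#' @return data frame `(assay_id, log2_fc, neg_log10_p, class)` with the
#'   guide lines attached as attribute `"guides"`
#' @export
volcano_coordinates <- function(diff, alpha = 0.10,
                                fc_low = 0.67, fc_high = 1.5) {
  if (nrow(diff) == 0) stop("empty differential table")
  keep <- diff$class != "excluded" & !is.na(diff$p_perm) & !is.na(diff$fc)
  out <- data.frame(
    assay_id = diff$assay_id[keep],
    log2_fc = diff$log2_fc[keep],
    neg_log10_p = -log10(diff$p_perm[keep]),
    class = diff$class[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "guides") <- list(
    p = alpha, neg_log10_p = -log10(alpha),
    log2_fc = c(down = log2(fc_low), up = log2(fc_high))
  )
  out
}

#' Render a volcano plot
#'
#' @param diff a `diff_table`
#' @param file optional output path (`.png`/`.pdf`/`.svg`); `NULL` returns
#'   the ggplot object
#' @inheritParams volcano_coordinates
#' @return a ggplot object, invisibly when written to file
#' @export
plot_volcano <- function(diff, file = NULL, alpha = 0.10,
                         fc_low = 0.67, fc_high = 1.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_volcano() needs the ggplot2 package")
  xy <- volcano_coordinates(diff, alpha, fc_low, fc_high)
  g <- attr(xy, "guides")
  p <- ggplot2::ggplot(xy, ggplot2::aes(x = log2_fc, y = neg_log10_p,
                                        colour = class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = g$neg_log10_p, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = unname(g$log2_fc),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      up = "#c0392b", down = "#2980b9", not_significant = "grey60")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 permutation p", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5)
    return(invisible(p))
  }
  p
}

#' Per-assay expression values by group, for box plots
#'
#' @param norm matrix from [normalize_expression()]
#' @param groups group vector or metadata data frame
#' @param assays assays to export (default: all columns of `norm`)
#' @return long data frame `(assay_id, sample_id, group, expression)`
#'   with complete cases only
#' @export
boxplot_data <- function(norm, groups, assays = colnames(norm)) {
  groups <- .as_group_vector(groups, rownames(norm))
  assays <- intersect(assays, colnames(norm))
  rows <- lapply(assays, function(a) {
    v <- norm[names(groups), a]
    data.frame(assay_id = a, sample_id = names(groups),
               group = unname(groups), expression = unname(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$expression), , drop = FALSE]
}
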