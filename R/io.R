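.guess_sep <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a wide-format Cq table
#'
#' Expects delimited text with sample ids in the first column and one column
#' per assay (the usual panel-export layout); `transpose = TRUE` accepts the
#' assay-per-row orientation some instruments emit. Blank cells and the
#' tokens in `na_tokens` mean "not detected" and become `NA`. Any other
#' non-numeric cell, a duplicated id, or a Cq outside (0, 45] is a hard
#' error naming the offending cell.
#'
#' @param path delimited text file (`.csv` comma, otherwise tab; override
#'   with `sep`)
#' @param annotation optional assay-role annotation: either a named character
#'   vector (`assay id -> role`) or a data frame with columns `assay_id` and
#'   `role`. Unannotated assays default to role `target`.
#' @param na_tokens cell values treated as "not detected"
#' @param sep field separator; default guessed from the extension
#' @param transpose set `TRUE` when rows are assays and columns samples
#' @return a [cq_matrix()]
#' @export
read_cq_table <- function(path, annotation = NULL,
                          na_tokens = c("", "NA", "Undetermined", "ND"),
                          sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("Cq table not found: ", path)
  sep <- sep %||% .guess_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "")
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  vals <- as.matrix(body)
  colnames(vals) <- colnames(raw)[-1]  # as.matrix uniquifies duplicates
  rownames(vals) <- ids
  vals[vals %in% na_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric Cq at row '%s', column '%s': \"%s\"",
                 rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]))
  if (transpose) num <- t(num)
  cq_matrix(num, .resolve_annotation(annotation))
}

.resolve_annotation <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  if (is.data.frame(annotation)) {
    if (!all(c("assay_id", "role") %in% names(annotation)))
      stop("annotation data frame needs columns `assay_id` and `role`")
    stats::setNames(as.character(annotation$role),
                    as.character(annotation$assay_id))
  } else {
    annotation
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Cq matrix back to delimited text
#'
#' Values are serialized with 17 significant digits so that
#' `read_cq_table(write_cq_table(x))` is the identity on both values and
#' missingness; missing wells are written as empty cells.
#'
#' @param x a `cq_matrix`
#' @param path output path (`.csv` comma, otherwise tab)
#' @param sep field separator override
#' @return `path`, invisibly
#' @export
write_cq_table <- function(x, path, sep = NULL) {
  sep <- sep %||% .guess_sep(path)
  chr <- array(sprintf("%.17g", x$cq), dim = dim(x$cq))
  chr[is.na(x$cq)] <- ""
  lines <- c(
    paste(c("sample_id", colnames(x$cq)), collapse = sep),
    vapply(seq_len(nrow(x$cq)), function(i) {
      paste(c(rownames(x$cq)[i], chr[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' The file must carry `sample_id` and `group` columns; anything else is kept
#' as a matching covariate (empty cells become `NA`, not an error). Group
#' tokens are mapped to `case` / `control` through `group_map`; a token the
#' map cannot resolve is an error.
#'
#' @param path delimited text file
#' @param group_map named character vector, token -> `"case"`/`"control"`.
#'   The default maps the clinical labels `HT` (hemorrhagic transformation)
#'   to case and `non-HT` to control, and passes already-canonical
#'   `case`/`control` tokens through.
#' @param case_insensitive match group tokens ignoring case
#' @param sep field separator; default guessed from extension
#' @return a data frame with columns `sample_id`, `group`, the covariates,
#'   `excluded` (logical) and `exclusion_reason`
#' @export
read_sample_metadata <- function(path,
                                 group_map = c("HT" = "case",
                                               "non-HT" = "control",
                                               "case" = "case",
                                               "control" = "control"),
                                 case_insensitive = FALSE,
                                 sep = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- sep %||% .guess_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata needs `sample_id` and `group` columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  tokens <- as.character(df$group)
  keys <- names(group_map)
  if (case_insensitive) {
    idx <- match(tolower(tokens), tolower(keys))
  } else {
    idx <- match(tokens, keys)
  }
  if (anyNA(idx))
    stop("unmappable group token(s): ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  df$group <- unname(group_map[idx])
  if (!all(df$group %in% c("case", "control")))
    stop("group_map values must be `case` or `control`")
  if (is.null(df$excluded)) df$excluded <- FALSE
  df$excluded <- as.logical(df$excluded)
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- ""
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  df
}

#' Check that metadata and Cq matrix describe the same samples
#'
#' @param x a `cq_matrix`
#' @param metadata data frame from [read_sample_metadata()]
#' @return invisibly `TRUE`; errors when a metadata sample has no Cq row or
#'   a non-excluded sample lacks a group
#' @export
validate_samples <- function(x, metadata) {
  missing <- setdiff(metadata$sample_id, sample_ids(x))
  if (length(missing))
    stop("metadata sample(s) absent from Cq matrix: ",
         paste(missing, collapse = ", "))
  ungrouped <- metadata$sample_id[!metadata$excluded & is.na(metadata$group)]
  if (length(ungrouped))
    stop("non-excluded sample(s) without group: ",
         paste(ungrouped, collapse = ", "))
  invisible(TRUE)
}

#' Write pipeline result files
#'
#' Emits `diff_table.tsv` (columns: assay, n_case, n_control, fc, log2_fc,
#' t_yuen, p_perm, p_adj, class), `qc_report.tsv` (a sample section and an
#' assay section, each introduced by a `##` header line) and
#' `run_manifest.json` echoing the configuration, the seed and the exclusion
#' log.
#'
#' @param diff_table data frame from [run_differential()]
#' @param qc_report a `qc_report` (see [build_qc_report()]), or `NULL`
#' @param out_dir output directory, created if needed
#' @param manifest named list written as the run manifest, or `NULL`
#' @return character vector of files written, invisibly
#' @export
write_results <- function(diff_table, qc_report, out_dir, manifest = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0)
    stop("cannot write to directory: ", out_dir)
  files <- character(0)

  dt <- diff_table
  names(dt)[names(dt) == "assay_id"] <- "assay"
  cols <- c("assay", "n_case", "n_control", "fc", "log2_fc",
            "t_yuen", "p_perm", "p_adj", "class")
  for (c0 in setdiff(cols, names(dt))) dt[[c0]] <- NA
  diff_path <- file.path(out_dir, "diff_table.tsv")
  utils::write.table(dt[, cols, drop = FALSE], diff_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, diff_path)

  if (!is.null(qc_report)) {
    qc_path <- file.path(out_dir, "qc_report.tsv")
    con <- file(qc_path, "w")
    writeLines("## samples", con)
    utils::write.table(qc_report$samples, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(c("", "## assays"), con)
    utils::write.table(qc_report$assays, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    files <- c(files, qc_path)
  }

  if (!is.null(manifest)) {
    man_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    files <- c(files, man_path)
  }
  invisible(files)
}
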