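# Small construction helpers shared across test files.

# Quick cq_matrix from a numeric matrix, naming samples s1..sn and assays
# a1..am unless dimnames are already present.
make_cq <- function(m, roles = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("a", seq_len(ncol(m)))
  cq_matrix(m, roles)
}

# Write a delimited Cq table to a temp file and return the path.
write_tmp_table <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

# Two-group metadata data frame.
make_groups <- function(case_ids, control_ids) {
  data.frame(
    sample_id = c(case_ids, control_ids),
    group = rep(c("case", "control"),
                c(length(case_ids), length(control_ids))),
    stringsAsFactors = FALSE
  )
}

# Independent step-up BH evaluation, used as the adjustment oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Second, independently coded Yuen-Welch evaluation (test oracle).
yuen_oracle <- function(x, y, trim) {
  comp <- function(v) {
    n <- length(v)
    g <- floor(trim * n)
    s <- sort(v)
    kept <- s[(g + 1):(n - g)]
    w <- c(rep(s[g + 1], g), kept, rep(s[n - g], g))
    h <- n - 2 * g
    list(tm = mean(kept), d = (n - 1) * var(w) / (h * (h - 1)))
  }
  a <- comp(x)
  b <- comp(y)
  (a$tm - b$tm) / sqrt(a$d + b$d)
}

# Independent greedy matcher used as the matching oracle: cases in
# descending score, each takes the closest remaining control (first in
# input order on ties).
greedy_oracle <- function(scores, case_ids, ctrl_ids) {
  ord <- case_ids[order(-scores[case_ids])]
  left <- ctrl_ids
  out <- NULL
  for (cid in ord) {
    if (!length(left)) break
    d <- abs(scores[left] - scores[cid])
    j <- which(d == min(d))[1]
    out <- rbind(out, data.frame(case_id = cid, control_id = left[j],
                                 stringsAsFactors = FALSE))
    left <- left[-j]
  }
  out
}

study_data_dir <- function() {
  file.path(system.file("extdata", package = "cqdiff"), "study")
}
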