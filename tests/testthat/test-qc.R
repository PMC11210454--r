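hemo_matrix <- function(cq23, cq451) {
  m <- cbind(`hsa-miR-23a-3p` = cq23, `hsa-miR-451a` = cq451)
  rownames(m) <- paste0("s", seq_along(cq23))
  cq_matrix(m, c(`hsa-miR-451a` = "hemolysis_marker"))
}

test_that("hemolysis dCq follows the strict > 7 rule", {
  x <- hemo_matrix(c(24.0, 31.26, 31.00, 32.68),
                   c(24.0, 24.00, 24.00, 24.00))
  h <- compute_hemolysis_dcq(x)
  expect_equal(h$dcq, c(0, 7.26, 7.00, 8.68))
  expect_equal(h$hemolysis_flag, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("a missing hemolysis marker yields NA with a warning", {
  x <- hemo_matrix(c(24, NA), c(20, 20))
  expect_warning(h <- compute_hemolysis_dcq(x), "missing marker")
  expect_true(is.na(h$dcq[2]) && is.na(h$hemolysis_flag[2]))
  expect_false(is.na(h$dcq[1]))
  expect_error(compute_hemolysis_dcq(hemo_matrix(24, 20),
                                     pair = c("nope", "hsa-miR-451a")),
               "not in matrix")
})

test_that("hemolysis flagging is monotone in contamination", {
  set.seed(11)
  for (i in 1:25) {
    c23 <- runif(1, 25, 33)
    c451 <- runif(1, 18, 26)
    x <- hemo_matrix(c23, c451)
    f0 <- compute_hemolysis_dcq(x)$hemolysis_flag
    # raise the constant marker or lower the RBC marker: contamination up
    x_up <- hemo_matrix(c23 + runif(1, 0, 5), c451 - runif(1, 0, 5))
    f1 <- compute_hemolysis_dcq(x_up)$hemolysis_flag
    if (f0) expect_true(f1)
  }
})

test_that("spike-in report warns only beyond the window", {
  m <- matrix(c(rep(20, 5), rep(25, 5)), 5, 2,
              dimnames = list(paste0("s", 1:5), c("UniSp2", "UniSp4")))
  x <- cq_matrix(m, c(UniSp2 = "spike_in", UniSp4 = "spike_in"))
  rep0 <- spike_in_report(x)
  expect_false(any(rep0$warn))

  m2 <- m
  m2["s3", "UniSp2"] <- 23  # +3 cycles from the median
  x2 <- cq_matrix(m2, c(UniSp2 = "spike_in", UniSp4 = "spike_in"))
  rep2 <- spike_in_report(x2, window = 2)
  expect_equal(rep2$sample_id[rep2$warn], "s3")
  expect_equal(rep2$assay_id[rep2$warn], "UniSp2")

  # partial annotation: only UniSp4 present on the panel
  x3 <- cq_matrix(m[, "UniSp4", drop = FALSE], c(UniSp4 = "spike_in"))
  rep3 <- spike_in_report(x3)
  expect_setequal(unique(rep3$assay_id), "UniSp4")

  x4 <- make_cq(matrix(25, 2, 2))
  expect_warning(rep4 <- spike_in_report(x4), "no spike-in")
  expect_equal(nrow(rep4), 0L)
})

ref_matrix <- function(means) {
  # one reference assay equal to the desired per-sample mean
  m <- cbind(ref1 = means, tgt = rep(25, length(means)))
  rownames(m) <- paste0("s", seq_along(means))
  cq_matrix(m, c(ref1 = "reference"))
}

test_that("reference outlier sample detection flags the degraded sample", {
  x <- ref_matrix(c(29.0, 29.5, 30.03, 34.67))
  for (rule in c("robust_z", "gap")) {
    out <- detect_reference_outlier_samples(x, "ref1", rule = rule)
    expect_equal(out$sample_id[out$flag], "s4", info = rule)
  }
  expect_equal(
    out$mean_reference_cq[out$sample_id == "s4"], 34.67)
})

test_that("outlier detection handles degenerate spreads", {
  same <- ref_matrix(rep(30, 6))
  expect_false(any(detect_reference_outlier_samples(same, "ref1")$flag))

  single <- ref_matrix(30)
  expect_warning(out <- detect_reference_outlier_samples(single, "ref1"),
                 "only one sample")
  expect_false(any(out$flag))

  m <- cbind(ref1 = c(NA, 30, 31), tgt = c(25, 25, 25))
  rownames(m) <- paste0("s", 1:3)
  x <- cq_matrix(m, c(ref1 = "reference"))
  out <- detect_reference_outlier_samples(x, "ref1")
  expect_true(out$flag[1])
  expect_equal(out$reason[1], "no_reference_signal")
})

test_that("missingness filter is strict and exempts non-target roles", {
  n <- 20
  m <- matrix(25, n, 4,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("gone", "boundary", "clean", "ref")))
  m[1:11, "gone"] <- NA       # 0.55 missing -> excluded
  m[1:10, "boundary"] <- NA   # exactly 0.50 -> retained
  m[1:15, "ref"] <- NA        # exempt role, reported only
  x <- cq_matrix(m, c(ref = "reference"))
  res <- apply_missingness_filter(x, 0.5)
  expect_equal(res$excluded, "gone")
  expect_setequal(res$retained, c("boundary", "clean"))
  tab <- res$table
  expect_equal(tab$missing_fraction[tab$assay_id == "ref"], 0.75)
  expect_false(tab$excluded[tab$assay_id == "ref"])
  expect_equal(tab$reason[tab$assay_id == "gone"], "missingness")
})

test_that("manual exclusions remove entities once and reject unknown ids", {
  x <- make_cq(matrix(25, 3, 3))
  ex <- data.frame(id = "a2", kind = "assay",
                   reason = "nonspecific_amplification")
  res <- apply_manual_exclusions(x, ex)
  expect_equal(ncol(res$cq$cq), 2L)
  expect_equal(res$log$reason, "nonspecific_amplification")

  unchanged <- apply_manual_exclusions(x, NULL)
  expect_identical(unchanged$cq$cq, x$cq)

  dup <- rbind(ex, ex)
  res2 <- apply_manual_exclusions(x, dup)
  expect_equal(nrow(res2$log), 1L)
  expect_equal(ncol(res2$cq$cq), 2L)

  bad <- data.frame(id = "ghost", kind = "sample", reason = "why")
  expect_error(apply_manual_exclusions(x, bad), "unknown id")
})

test_that("missingness filter and manual exclusions commute", {
  set.seed(3)
  m <- matrix(runif(60, 20, 36), 6, 10)
  m[sample(60, 20)] <- NA
  x <- make_cq(m)
  ex <- data.frame(id = c("a3", "s2"), kind = c("assay", "sample"),
                   reason = "manual")

  # manual first, then missingness
  r1 <- apply_manual_exclusions(x, ex)
  f1 <- apply_missingness_filter(r1$cq, 0.5)
  # missingness computed on post-manual samples in both orders
  r2cq <- subset_cq(x, samples = setdiff(sample_ids(x), "s2"))
  f2 <- apply_missingness_filter(r2cq, 0.5)
  kept2 <- setdiff(f2$retained, "a3")
  expect_setequal(f1$retained, kept2)
})

test_that("qc report assembles sample and assay sections", {
  x <- hemo_matrix(c(24, 32), c(24, 24))
  h <- compute_hemolysis_dcq(x)
  tab <- data.frame(assay_id = "m1", role = "target",
                    missing_fraction = 0.6, excluded = TRUE,
                    reason = "missingness", stringsAsFactors = FALSE)
  man <- data.frame(id = "m2", kind = "assay",
                    reason = "nonspecific_amplification",
                    stringsAsFactors = FALSE)
  qc <- build_qc_report(h, assay_table = tab, manual_log = man)
  expect_s3_class(qc, "qc_report")
  expect_equal(sum(qc$assays$excluded), 2L)
  expect_true(all(nzchar(qc$assays$reason[qc$assays$excluded])))
  out <- tempfile()
  write_results(cqdiff:::.empty_diff_table(), qc, out)
  txt <- readLines(file.path(out, "qc_report.tsv"))
  expect_true("## samples" %in% txt && "## assays" %in% txt)
})
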