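norm_fixture <- function(n_per_group = 5, n_assays = 6, seed = 30,
                         delta = NULL) {
  set.seed(seed)
  ids <- c(paste0("c", seq_len(n_per_group)),
           paste0("n", seq_len(n_per_group)))
  e <- matrix(2^rnorm(2 * n_per_group * n_assays, sd = 0.5),
              nrow = 2 * n_per_group,
              dimnames = list(ids, paste0("m", seq_len(n_assays))))
  if (!is.null(delta)) {
    for (a in names(delta))
      e[seq_len(n_per_group), a] <- e[seq_len(n_per_group), a] * 2^delta[[a]]
  }
  list(norm = e,
       groups = make_groups(paste0("c", seq_len(n_per_group)),
                            paste0("n", seq_len(n_per_group))))
}

test_that("identical groups give fc 1 and no calls", {
  ids <- c(paste0("c", 1:4), paste0("n", 1:4))
  e <- matrix(rep(c(1, 2, 3, 4), times = 2), nrow = 8, ncol = 3,
              dimnames = list(ids, paste0("m", 1:3)))
  res <- run_differential(e, make_groups(paste0("c", 1:4), paste0("n", 1:4)),
                          analysis_config(n_permutations = 200))
  expect_equal(res$fc, rep(1, 3))
  expect_equal(res$class, rep("not_significant", 3))
  expect_equal(res$t_yuen, rep(0, 3))
})

test_that("classification uses strict thresholds on raw p and fc", {
  expect_equal(classify_dysregulation(0.23, 0.005), "down")
  expect_equal(classify_dysregulation(2.01, 0.026), "up")
  expect_equal(classify_dysregulation(1.2, 0.01), "not_significant")
  expect_equal(classify_dysregulation(0.5, 0.5), "not_significant")
  # boundaries are strict in all three places
  expect_equal(classify_dysregulation(0.67, 0.01), "not_significant")
  expect_equal(classify_dysregulation(1.5, 0.01), "not_significant")
  expect_equal(classify_dysregulation(0.2, 0.10), "not_significant")
  expect_equal(classify_dysregulation(c(NA, 2), c(0.01, NA)),
               c("excluded", "excluded"))
})

test_that("a strong injected effect is detected and classified", {
  fx <- norm_fixture(n_per_group = 10, n_assays = 8, seed = 31,
                     delta = list(m3 = -2))
  res <- run_differential(fx$norm, fx$groups,
                          analysis_config(n_permutations = 500))
  row <- res[res$assay_id == "m3", ]
  expect_equal(row$class, "down")
  expect_lt(row$fc, 0.67)
  expect_lt(row$p_perm, 0.1)
})

test_that("BH column dominates raw p and classification ignores it", {
  fx <- norm_fixture(n_per_group = 6, n_assays = 10, seed = 32,
                     delta = list(m1 = -2.5))
  res <- run_differential(fx$norm, fx$groups,
                          analysis_config(n_permutations = 400))
  expect_true(all(res$p_adj >= res$p_perm - 1e-12))
  expect_true(all(which(res$p_adj < 0.1) %in% which(res$p_perm < 0.1)))
  expect_equal(res$p_adj, bh_adjust(res$p_perm))
})

test_that("swapping case and control mirrors the classification", {
  fx <- norm_fixture(n_per_group = 8, n_assays = 5, seed = 33,
                     delta = list(m2 = 2.5, m4 = -2.5))
  cfg <- analysis_config(n_permutations = 500)
  res1 <- run_differential(fx$norm, fx$groups, cfg)
  swapped <- fx$groups
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  res2 <- run_differential(fx$norm, swapped, cfg)
  expect_equal(res2$fc, 1 / res1$fc)
  expect_equal(res1$class[res1$assay_id == "m2"], "up")
  expect_equal(res2$class[res2$assay_id == "m2"], "down")
  expect_equal(res1$class[res1$assay_id == "m4"], "down")
  expect_equal(res2$class[res2$assay_id == "m4"], "up")
})

test_that("assays without enough complete cases are excluded with a note", {
  fx <- norm_fixture(n_per_group = 4, n_assays = 3, seed = 34)
  fx$norm[c("c1", "c2", "c3"), "m2"] <- NA  # one case value left
  res <- run_differential(fx$norm, fx$groups,
                          analysis_config(n_permutations = 100))
  row <- res[res$assay_id == "m2", ]
  expect_equal(row$class, "excluded")
  expect_equal(row$note, "insufficient_complete_cases")
  expect_true(is.na(row$p_perm))
  expect_equal(nrow(res), 3L)  # every assay appears exactly once
})

test_that("per-assay p-values are reproducible and order-independent", {
  fx <- norm_fixture(n_per_group = 6, n_assays = 6, seed = 35)
  cfg <- analysis_config(n_permutations = 300)
  res1 <- run_differential(fx$norm, fx$groups, cfg)
  res2 <- run_differential(fx$norm, fx$groups, cfg)
  expect_identical(res1$p_perm, res2$p_perm)
})

test_that("volcano coordinates are exact logs with guide lines", {
  d <- cqdiff:::.empty_diff_table()
  d[1, ] <- list("flat", 5L, 5L, 1, 0, 0, 1, 1, "not_significant", "")
  d[2, ] <- list("hit", 5L, 5L, 2, 1, 3, 0.01, 0.05, "up", "")
  d[3, ] <- list("dead", 5L, 5L, NA, NA, NA, NA, NA, "excluded",
                 "insufficient_complete_cases")
  xy <- volcano_coordinates(d)
  expect_equal(nrow(xy), 2L)
  expect_equal(xy[xy$assay_id == "flat", c("log2_fc", "neg_log10_p")],
               data.frame(log2_fc = 0, neg_log10_p = 0, row.names = 1L))
  expect_equal(xy$log2_fc[xy$assay_id == "hit"], 1.0)
  expect_equal(xy$neg_log10_p[xy$assay_id == "hit"], 2.0)
  g <- attr(xy, "guides")
  expect_equal(g$p, 0.1)
  expect_equal(unname(g$log2_fc), log2(c(0.67, 1.5)))
})

test_that("boxplot export is long-form complete cases", {
  fx <- norm_fixture(n_per_group = 3, n_assays = 2, seed = 36)
  fx$norm["c1", "m1"] <- NA
  long <- boxplot_data(fx$norm, fx$groups)
  expect_equal(nrow(long), 11L)
  expect_setequal(unique(long$group), c("case", "control"))
})
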