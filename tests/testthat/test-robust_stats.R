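test_that("trimmed mean removes floor(trim*n) per tail", {
  expect_equal(trimmed_mean(1:10, 0.1), mean(2:9))  # 5.5
  expect_equal(trimmed_mean(rep(3.7, 8), 0.3), 3.7)
  expect_equal(trimmed_mean(c(4, 1, 9), 0), mean(c(4, 1, 9)))
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1))
    g <- runif(1, 0, 0.49)
    expect_equal(trimmed_mean(x, g), mean(x, trim = g))
  }
  expect_error(trimmed_mean(c(1, 2), 0.5), "trim")
  expect_error(trimmed_mean(c(1, NA), 0.1), "missing")
})

test_that("winsorized variance matches hand winsorization", {
  expect_equal(winsorized_variance(rep(2, 6), 0.2), 0)
  x <- c(4, 1, 9, 2)
  expect_equal(winsorized_variance(x, 0), var(x))
  # (1,2,3,4,10), g=1 -> (2,2,3,4,4), var = 1
  expect_equal(winsorized_variance(c(1, 2, 3, 4, 10), 0.2), 1.0)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    n <- length(x)
    g <- floor(0.2 * n)
    s <- sort(x)
    w <- c(rep(s[g + 1], g), s[(g + 1):(n - g)], rep(s[n - g], g))
    expect_equal(winsorized_variance(x, 0.2), var(w))
  }
  expect_error(winsorized_variance(c(1, 2, 3), 0.4), "fewer than 2")
})

test_that("Yuen-Welch statistic reduces to Welch t and matches oracles", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  expect_equal(yuen_welch_statistic(x, x, 0.1), 0)
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(5:20, 1))
    b <- rnorm(sample(5:20, 1), 0.3)
    expect_equal(yuen_welch_statistic(a, b, 0),
                 unname(t.test(a, b)$statistic), tolerance = 1e-12)
    # dual-implementation checks: independent R oracle and the C++ engine
    expect_equal(yuen_welch_statistic(a, b, 0.1), yuen_oracle(a, b, 0.1))
    expect_equal(yuen_welch_statistic(a, b, 0.1),
                 cqdiff:::.yuen_statistic_cpp(a, b, 0.1))
  }
})

test_that("degenerate variances are handled as specified", {
  expect_equal(yuen_welch_statistic(c(2, 2, 2), c(2, 2, 2), 0), 0)
  expect_error(yuen_welch_statistic(c(1, 1, 1), c(2, 2, 2), 0),
               "degenerate variance")
  expect_error(yuen_welch_statistic(c(1, 2, 3), c(3, 4, 5), 0.4),
               "retain >= 2")
})

test_that("permutation test contract: determinism, bounds, RNG hygiene", {
  set.seed(8)
  x <- rnorm(10)
  y <- rnorm(10, 1)
  r1 <- permutation_yuen_test(x, y, 0.1, B = 500, seed = 99)
  r2 <- permutation_yuen_test(x, y, 0.1, B = 500, seed = 99)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_gte(r1$p_perm, 1 / 501)
  expect_lte(r1$p_perm, 1)

  # a seeded call must not disturb the caller's RNG stream
  set.seed(4)
  a <- runif(1)
  set.seed(4)
  invisible(permutation_yuen_test(x, y, 0.1, B = 50, seed = 1))
  expect_identical(runif(1), a)

  const <- rep(5, 6)
  expect_equal(permutation_yuen_test(const, const, 0.1, B = 100)$p_perm, 1)
  expect_error(permutation_yuen_test(1, 2, 0.1), "at least 4")
})

test_that("exhaustive enumeration gives the exact two-sided p", {
  r <- exhaustive_permutation_test(c(1, 2), c(3, 4), trim = 0)
  expect_equal(r$n_relabelings, 6)
  expect_equal(r$p_exact, 2 / 6)

  same <- exhaustive_permutation_test(c(1, 2, 3), c(1, 2, 3), trim = 0)
  expect_equal(same$p_exact, 1)

  set.seed(10)
  a <- rnorm(4); b <- rnorm(4, 1)
  expect_equal(exhaustive_permutation_test(a, b, 0.1)$p_exact,
               exhaustive_permutation_test(b, a, 0.1)$p_exact)
  expect_error(exhaustive_permutation_test(rnorm(15), rnorm(15), 0),
               "cap")
})

test_that("Monte-Carlo p approaches the exhaustive p", {
  set.seed(12)
  x <- rnorm(4); y <- rnorm(4, 1.5)
  exact <- exhaustive_permutation_test(x, y, 0.1)$p_exact
  mc <- permutation_yuen_test(x, y, 0.1, B = 20000, seed = 3)$p_perm
  expect_lt(abs(mc - exact), 0.02)
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:60, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  p_na <- c(0.01, NA, 0.5)
  adj <- bh_adjust(p_na)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("trimming tempers the influence of a gross outlier", {
  set.seed(14)
  d_welch <- d_yuen <- numeric(30)
  for (i in 1:30) {
    x <- rnorm(10); y <- rnorm(10)
    x_out <- c(x, 10)  # one extra observation 10 SD out
    d_welch[i] <- abs(yuen_welch_statistic(x_out, y, 0) -
                        yuen_welch_statistic(x, y, 0))
    d_yuen[i] <- abs(yuen_welch_statistic(x_out, y, 0.1) -
                       yuen_welch_statistic(x, y, 0.1))
  }
  # over the battery, the trimmed statistic moves far less than Welch
  expect_lt(mean(d_yuen), mean(d_welch))
  expect_lt(median(d_yuen), median(d_welch))
  expect_lt(mean(d_yuen) / mean(d_welch), 0.5)
})

test_that("power is monotone in effect size", {
  set.seed(15)
  power_at <- function(delta, nrep = 150) {
    mean(replicate(nrep, {
      permutation_yuen_test(rnorm(10, delta), rnorm(10), 0.1,
                            B = 200)$p_perm < 0.05
    }))
  }
  pw <- vapply(c(0, 0.75, 1.5, 2.5), power_at, numeric(1))
  # allow small simulation wiggle between adjacent effect sizes
  expect_true(all(diff(pw) > -0.05))
  expect_lt(pw[1], 0.12)
  expect_gt(pw[4], 0.9)
})
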