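#' Trimmed mean
#'
#' Mean of the central order statistics after removing `g = floor(trim * n)`
#' observations from each tail. `trim = 0` is the ordinary mean.
#'
#' @param x numeric vector, no missing values
#' @param trim trim proportion gamma in [0, 0.5)
#' @return scalar
#' @export
trimmed_mean <- function(x, trim = 0.1) {
  .check_trim_args(x, trim)
  n <- length(x)
  g <- floor(trim * n)
  if (n - 2 * g < 1)
    stop("trimming removes every observation (n = ", n, ", trim = ", trim, ")")
  s <- sort(x)
  mean(s[(g + 1):(n - g)])
}

#' Winsorized sample variance
#'
#' Variance (divisor `n - 1`) after replacing the `g = floor(trim * n)`
#' smallest values by the `(g+1)`-th order statistic and the `g` largest by
#' the `(n-g)`-th. This is the spread estimate entering Yuen's standard
#' error; `trim = 0` reduces to the ordinary sample variance.
#'
#' @inheritParams trimmed_mean
#' @return scalar
#' @export
winsorized_variance <- function(x, trim = 0.1) {
  .check_trim_args(x, trim)
  n <- length(x)
  if (n < 2) stop("need n >= 2 for a variance")
  g <- floor(trim * n)
  if (n - 2 * g < 2)
    stop("fewer than 2 retained values after trimming")
  s <- sort(x)
  w <- s
  if (g > 0) {
    w[1:g] <- s[g + 1]
    w[(n - g + 1):n] <- s[n - g]
  }
  stats::var(w)
}

.check_trim_args <- function(x, trim) {
  if (!is.numeric(x) || length(x) < 1) stop("`x` must be non-empty numeric")
  if (anyNA(x)) stop("`x` must not contain missing values")
  if (!(trim >= 0 && trim < 0.5)) stop("`trim` must lie in [0, 0.5)")
  invisible(TRUE)
}

#' Yuen-Welch statistic for two trimmed means
#'
#' `T = (tmean(x) - tmean(y)) / sqrt(d_x + d_y)` with Yuen's squared
#' standard errors `d_j = (n_j - 1) * s2w_j / (h_j * (h_j - 1))`, where
#' `s2w_j` is the Winsorized variance and `h_j = n_j - 2*g_j` the retained
#' count. At `trim = 0` this is exactly the Welch unequal-variance t
#' statistic. Both groups must retain at least two values.
#'
#' @param x,y numeric vectors (no missing values)
#' @param trim trim proportion gamma
#' @return scalar; 0 when both terms of a zero denominator pair with equal
#'   trimmed means; an error when the denominator is zero but the trimmed
#'   means differ (degenerate variance)
#' @export
yuen_welch_statistic <- function(x, y, trim = 0.1) {
  .check_trim_args(x, trim)
  .check_trim_args(y, trim)
  nx <- length(x)
  ny <- length(y)
  gx <- floor(trim * nx)
  gy <- floor(trim * ny)
  hx <- nx - 2 * gx
  hy <- ny - 2 * gy
  if (hx < 2 || hy < 2)
    stop("each group must retain >= 2 values after trimming")
  d_of <- function(v, n, g, h) (n - 1) * winsorized_variance(v, trim) / (h * (h - 1))
  dx <- d_of(x, nx, gx, hx)
  dy <- d_of(y, ny, gy, hy)
  diff <- trimmed_mean(x, trim) - trimmed_mean(y, trim)
  if (dx + dy == 0) {
    if (diff == 0) return(0)
    stop("degenerate variance: zero Yuen standard error with unequal trimmed means")
  }
  diff / sqrt(dx + dy)
}

# Permutation-safe variant: degenerate unequal-mean case maps to +/-Inf so
# a relabeling can never error mid-loop (mirrors the C++ engine).
.yuen_safe <- function(x, y, trim) {
  .yuen_statistic_cpp(as.numeric(x), as.numeric(y), trim)
}

#' Permutation Yuen-Welch test
#'
#' Pools the two groups, draws `B` random relabelings preserving the group
#' sizes (without replacement — true permutations), recomputes the
#' Yuen-Welch statistic for each, and returns the two-sided add-one
#' permutation p-value `p = (1 + #{|T*| >= |T_obs|}) / (B + 1)`, which is
#' never exactly zero. With a seed the draw sequence is reproducible and the
#' caller's RNG state is left untouched.
#'
#' @param x,y numeric vectors; missing values are dropped
#' @param trim trim proportion gamma (default 0.10)
#' @param B number of permutations (default 1000)
#' @param seed integer seed, or `NULL` to continue the current RNG stream
#' @return object of class `perm_test`: list with `t_obs`, `p_perm`, `B`,
#'   `n_x`, `n_y`, `trim`, `seed`
#' @export
permutation_yuen_test <- function(x, y, trim = 0.1, B = 1000, seed = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx + ny < 4) stop("need a pooled sample size of at least 4")
  if (B < 1) stop("B must be >= 1")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(structure(list(t_obs = 0, p_perm = 1, B = as.integer(B),
                          n_x = nx, n_y = ny, trim = trim, seed = seed),
                     class = "perm_test"))
  }
  t_obs <- .yuen_safe(x, y, trim)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  abs_t <- .perm_yuen_abs_cpp(pooled, nx, as.integer(B), trim)
  count <- sum(abs_t >= abs(t_obs) - 1e-12)
  structure(list(t_obs = t_obs, p_perm = (1 + count) / (B + 1),
                 B = as.integer(B), n_x = nx, n_y = ny, trim = trim,
                 seed = seed),
            class = "perm_test")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation Yuen-Welch test: T = %.4f, p = %.4g (B = %d, trim = %g, n = %d vs %d)\n",
    x$t_obs, x$p_perm, x$B, x$trim, x$n_x, x$n_y))
  invisible(x)
}

#' Exhaustive permutation Yuen-Welch test
#'
#' Enumerates every relabeling of the pooled sample into groups of the
#' original sizes and reports the exact two-sided p-value
#' `#{|T*| >= |T_obs|} / C(n, n_x)` (the identity relabeling is always
#' counted, so p >= 1/C). Intended as the exact reference for the
#' Monte-Carlo test at small n; refuses more than a million relabelings.
#'
#' @inheritParams permutation_yuen_test
#' @return list with `t_obs`, `p_exact`, `n_relabelings`
#' @export
exhaustive_permutation_test <- function(x, y, trim = 0.1) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  n <- nx + length(y)
  n_comb <- choose(n, nx)
  if (n_comb > 1e6)
    stop("C(", n, ", ", nx, ") = ", n_comb,
         " relabelings exceed the enumeration cap; use permutation_yuen_test()")
  pooled <- c(x, y)
  t_obs <- .yuen_safe(x, y, trim)
  idx <- utils::combn(n, nx)
  abs_t <- apply(idx, 2, function(i) {
    abs(.yuen_safe(pooled[i], pooled[-i], trim))
  })
  count <- sum(abs_t >= abs(t_obs) - 1e-12)
  list(t_obs = t_obs, p_exact = count / n_comb, n_relabelings = n_comb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Missing entries are excluded
#' from the family size `m` and returned as missing; values outside [0, 1]
#' are an error.
#'
#' @param pvalues numeric vector of p-values, possibly with `NA`
#' @return adjusted p-values, same length and order as the input
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}
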