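#' Fit a propensity model for case status
#'
#' Main-effects logistic regression of case status on the matching
#' covariates; the fitted probabilities are the propensity scores. Factor
#' and character covariates are expanded to indicators, constant covariates
#' are dropped with a warning, and perfect separation triggers a
#' ridge-penalized refit (so scores stay strictly inside (0, 1)). Samples
#' with any missing covariate are dropped with a warning and receive no
#' score.
#'
#' @param covariates data frame of covariates, one row per sample; row
#'   names (or a `sample_id` column) identify samples
#' @param group named `sample_id -> "case"/"control"` vector or a metadata
#'   data frame
#' @return named numeric vector of propensity scores in (0, 1), one per
#'   scored sample, with attribute `"dropped"` listing unscored samples
#' @export
fit_propensity <- function(covariates, group) {
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  if (is.null(rownames(covariates)))
    stop("covariates need sample ids as rownames or a sample_id column")
  group <- .as_group_vector(group, rownames(covariates))
  covariates <- covariates[names(group), , drop = FALSE]
  if (ncol(covariates) < 1) stop("need at least one covariate")

  complete <- stats::complete.cases(covariates)
  if (!all(complete))
    warning("dropping sample(s) with missing covariates from matching: ",
            paste(rownames(covariates)[!complete], collapse = ", "))
  dropped <- rownames(covariates)[!complete]
  covariates <- covariates[complete, , drop = FALSE]
  group <- group[complete]
  if (!any(group == "case") || !any(group == "control"))
    stop("both groups must be non-empty after covariate filtering")

  is_const <- vapply(covariates,
                     function(v) length(unique(v)) <= 1, logical(1))
  if (any(is_const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[is_const], collapse = ", "))
    covariates <- covariates[, !is_const, drop = FALSE]
  }
  y <- as.integer(group == "case")
  if (ncol(covariates) == 0) {
    scores <- rep(mean(y), length(y))  # intercept-only
  } else {
    dat <- cbind(.y = y, covariates)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                       family = stats::binomial()))
    scores <- unname(stats::fitted(fit))
    eps <- 1e-8
    if (!fit$converged || any(scores < eps | scores > 1 - eps)) {
      warning("(near-)separation in propensity model; using ridge-penalized fit")
      mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
      if (ncol(mm) < 2) mm <- cbind(mm, .zero = 0)  # glmnet needs >= 2 columns
      rfit <- glmnet::glmnet(mm, y, family = "binomial", alpha = 0,
                             lambda = 0.1, standardize = TRUE)
      scores <- as.numeric(stats::predict(rfit, newx = mm, type = "response"))
    }
  }
  names(scores) <- names(group)
  attr(scores, "dropped") <- dropped
  scores
}

#' Greedy 1:k nearest-neighbour matching without replacement
#'
#' Cases are processed in descending propensity order (ties broken by input
#' order — greedy matching is order-dependent, so the order is fixed and
#' documented). Each case takes its `k` nearest-score controls among those
#' not yet used; a control is never reused. With a caliper, controls
#' farther than `caliper` (non-strict) are off limits and a case that finds
#' none is recorded unmatched.
#'
#' @param scores named propensity vector from [fit_propensity()]
#' @param group named group vector or metadata data frame
#' @param k controls per case (default 1)
#' @param caliper maximum allowed |score distance|, or `NULL` for none
#' @param logit_distance measure distance on the logit rather than the
#'   probability scale
#' @return object of class `match_result`: list with `pairs`
#'   (`case_id, control_id, distance`), `unmatched` (case ids), and
#'   `propensity`
#' @export
knn_match <- function(scores, group, k = 1, caliper = NULL,
                      logit_distance = FALSE) {
  group <- .as_group_vector(group, names(scores))
  scores <- scores[names(group)]
  if (any(!is.finite(scores))) stop("propensity scores must be finite")
  d_scale <- if (logit_distance) stats::qlogis(scores) else scores
  names(d_scale) <- names(scores)

  case_ids <- names(group)[group == "case"]
  ctrl_ids <- names(group)[group == "control"]
  # descending score, stable for ties (radix preserves input order)
  case_ids <- case_ids[order(-scores[case_ids], seq_along(case_ids),
                             method = "radix")]
  available <- ctrl_ids
  pairs <- list()
  unmatched <- character(0)
  for (cid in case_ids) {
    got <- 0L
    for (rep_i in seq_len(k)) {
      if (length(available) == 0) break
      d <- abs(d_scale[available] - d_scale[cid])
      best <- which.min(d)  # first minimum wins on ties (input order)
      if (!is.null(caliper) && d[best] > caliper) break
      pairs[[length(pairs) + 1L]] <- data.frame(
        case_id = cid, control_id = available[best],
        distance = unname(d[best]), stringsAsFactors = FALSE)
      available <- available[-best]
      got <- got + 1L
    }
    if (got == 0L) unmatched <- c(unmatched, cid)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case_id = character(0), control_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, unmatched = unmatched,
                 propensity = scores),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d unmatched case(s)\n",
              nrow(x$pairs), length(x$unmatched)))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference per covariate,
#' `SMD = (mean_case - mean_control) / sqrt((var_case + var_control) / 2)`,
#' computed pre-match on all samples and post-match on the paired samples
#' only. Factor covariates are expanded to indicator columns. A covariate
#' with zero pooled variance gets SMD 0 when the group means agree and `NA`
#' (non-evaluable) otherwise.
#'
#' @param covariates data frame as in [fit_propensity()]
#' @param group named group vector or metadata data frame
#' @param pairs `pairs` data frame of a [knn_match()] result
#' @return data frame `(covariate, smd_pre, smd_post)`
#' @export
balance_diagnostics <- function(covariates, group, pairs) {
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  group <- .as_group_vector(group, rownames(covariates))
  if (nrow(pairs) < 1) stop("need at least one matched pair")
  mm <- stats::model.matrix(~ . - 1, data = covariates[names(group), ,
                                                       drop = FALSE])
  smd_of <- function(ids_case, ids_ctrl) {
    vapply(colnames(mm), function(cv) {
      a <- mm[ids_case, cv]
      b <- mm[ids_ctrl, cv]
      s2 <- (stats::var(a) + stats::var(b)) / 2
      dm <- mean(a) - mean(b)
      if (is.na(s2) || s2 == 0) {
        if (dm == 0) 0 else NA_real_
      } else {
        dm / sqrt(s2)
      }
    }, numeric(1))
  }
  pre <- smd_of(names(group)[group == "case"],
                names(group)[group == "control"])
  post <- smd_of(pairs$case_id, pairs$control_id)
  data.frame(covariate = colnames(mm), smd_pre = unname(pre),
             smd_post = unname(post), stringsAsFactors = FALSE)
}

#' One-call propensity matching
#'
#' Convenience wrapper: fit the propensity model, run greedy 1:k matching,
#' and attach balance diagnostics.
#'
#' @inheritParams fit_propensity
#' @inheritParams knn_match
#' @return a `match_result` with an extra `balance` element
#' @export
match_cohort <- function(covariates, group, k = 1, caliper = NULL,
                         logit_distance = FALSE) {
  scores <- fit_propensity(covariates, group)
  res <- knn_match(scores, group, k = k, caliper = caliper,
                   logit_distance = logit_distance)
  res$balance <- balance_diagnostics(covariates, group, res$pairs)
  res
}
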