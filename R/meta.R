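#' Construct a table of study-level records for pooling
#'
#' Builds the study-level input to [pool_random_effects()]: one row per study
#' with its point estimate (a mean or a proportion), its within-study
#' variance, and its sample size. When `variance` is missing for a
#' proportion-type record it defaults to the binomial plug-in `p * (1 - p) / n`.
#'
#' @param study_id character vector of study labels.
#' @param estimate numeric vector of study means or proportions.
#' @param variance numeric vector of within-study variances (>= 0). May be
#'   `NA` for proportion records, in which case `p (1 - p) / n` is used.
#' @param n positive integer vector of study sample sizes.
#' @param type `"mean"` or `"proportion"`; proportions must lie in `[0, 1]`.
#' @return A `data.frame` of class `study_records` with columns
#'   `study_id`, `estimate`, `variance`, `n` and a `type` attribute.
#' @examples
#' study_records(c("a", "b"), estimate = c(0.10, 0.14), n = c(120, 80),
#'               type = "proportion")
#' @export
study_records <- function(study_id, estimate, variance = NULL, n,
                          type = c("mean", "proportion")) {
  type <- match.arg(type)
  k <- length(estimate)
  stopifnot(length(study_id) == k, length(n) == k)
  if (is.null(variance)) variance <- rep(NA_real_, k)
  stopifnot(length(variance) == k)
  if (!all(n >= 1)) stop("every study 'n' must be a positive integer")
  if (type == "proportion") {
    if (any(estimate < 0 | estimate > 1))
      stop("proportion estimates must lie in [0, 1]")
    miss <- is.na(variance)
    variance[miss] <- estimate[miss] * (1 - estimate[miss]) / n[miss]
  }
  if (any(is.na(variance)))
    stop("'variance' is required for mean-type records")
  if (any(variance < 0)) stop("variances must be non-negative")
  out <- data.frame(study_id = as.character(study_id),
                    estimate = as.numeric(estimate),
                    variance = as.numeric(variance),
                    n = as.integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "type") <- type
  class(out) <- c("study_records", "data.frame")
  out
}

#' Read study-level records from a delimited file
#'
#' Expects columns `study_id`, `estimate`, `variance`, `n`; `variance` may be
#' empty for proportion records.
#'
#' @param path path to a CSV file.
#' @inheritParams study_records
#' @return A `study_records` data frame.
#' @export
read_study_records <- function(path, type = c("mean", "proportion")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "estimate", "n")
  if (!all(need %in% names(x)))
    stop("study file must have columns study_id, estimate, n (and optionally variance)")
  v <- if ("variance" %in% names(x)) x$variance else NULL
  study_records(x$study_id, x$estimate, v, x$n, type = match.arg(type))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools study-level means or proportions with the method-of-moments
#' between-study variance estimator. With inverse-variance weights
#' \eqn{w_i = 1/v_i}, the heterogeneity statistic is
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2} and
#' \deqn{\tau^2 = \max\left(0, \frac{Q - (k - 1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),}
#' after which the pooled estimate uses weights \eqn{w_i^* = 1/(v_i + \tau^2)}.
#' When \eqn{Q \le k - 1} the estimator truncates at \eqn{\tau^2 = 0} and the
#' pool reduces to the fixed-effect inverse-variance mean.
#'
#' @param records a [study_records()] data frame with at least two rows.
#' @return A list of class `meta_pool`: `estimate`, `tau2`, `se`, `Q`, `k`,
#'   and the per-study random-effects `weights` (normalised to sum to 1).
#' @examples
#' recs <- study_records(letters[1:3], estimate = c(0.10, 0.11, 0.12),
#'                       variance = rep(0.001, 3), n = rep(100, 3))
#' pool_random_effects(recs)
#' @export
pool_random_effects <- function(records) {
  est <- records$estimate
  v <- records$variance
  k <- length(est)
  if (k < 2) stop("at least 2 studies are required for pooling")
  if (any(!is.finite(v))) stop("all variances must be finite")
  if (all(v == 0)) stop("all-zero variances: weights are undefined")
  # a single zero variance gets a large finite weight so it dominates smoothly
  w <- 1 / pmax(v, .Machine$double.eps)
  ybar <- sum(w * est) / sum(w)
  Q <- sum(w * (est - ybar)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (Q - (k - 1)) / denom) else 0
  wstar <- 1 / (pmax(v, .Machine$double.eps) + tau2)
  pooled <- sum(wstar * est) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  structure(list(estimate = pooled, tau2 = tau2, se = se, Q = Q, k = k,
                 weights = wstar / sum(wstar)),
            class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, ...) {
  cat("Random-effects pool (DerSimonian-Laird)\n")
  cat(sprintf("  k = %d studies, pooled estimate = %.4f (SE %.4f)\n",
              x$k, x$estimate, x$se))
  cat(sprintf("  Q = %.3f, tau^2 = %.5f\n", x$Q, x$tau2))
  invisible(x)
}
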