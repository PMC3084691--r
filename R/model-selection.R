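#' Harmonic-mean estimate of the log marginal likelihood
#'
#' The classic (Newton-Raftery) estimator: the harmonic mean of the
#' sampled likelihoods along a post-burn-in MCMC chain approximates the
#' marginal likelihood.  Computed entirely in log space as
#' `-(logSumExp(-lnL) - log n)`, so chains with log-likelihoods around
#' -1e4 pose no under/overflow problem.  The estimator is notoriously
#' unstable (it is dominated by the smallest sampled likelihood); see
#' [hm_stability()] for a per-run spread diagnostic.
#'
#' @param lnL numeric vector of sampled log-likelihoods (finite,
#'   non-empty).
#' @return The log marginal likelihood estimate (scalar).  Always lies in
#'   `[min(lnL), max(lnL)]`.
#' @export
harmonic_mean_lnL <- function(lnL) {
  if (!length(lnL)) stop("empty log-likelihood sample")
  if (any(!is.finite(lnL))) stop("non-finite log-likelihoods")
  -(.logsumexp(-lnL) - log(length(lnL)))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Per-run stability of the harmonic-mean estimate
#'
#' Computes the harmonic mean per run and on the pooled sample; a spread
#' of per-run values above `warn_spread` log units triggers a warning,
#' the usual symptom of the estimator's heavy-tailed behaviour.
#'
#' @param lnL vector of log-likelihoods.
#' @param run factor/vector of run identifiers, parallel to `lnL`.
#' @param warn_spread spread (max - min of per-run estimates) above which
#'   to warn, default 2.
#' @return List with `pooled` (the headline estimate), `per_run` (named
#'   vector) and `spread`.
#' @export
hm_stability <- function(lnL, run, warn_spread = 2) {
  per_run <- vapply(split(lnL, run), harmonic_mean_lnL, numeric(1))
  spread <- diff(range(per_run))
  if (is.finite(spread) && spread > warn_spread)
    warning(sprintf(
      "harmonic-mean estimates differ by %.2f log units across runs", spread))
  list(pooled = harmonic_mean_lnL(lnL), per_run = per_run, spread = spread)
}

#' Bayes factor between two models (2 delta-lnL convention)
#'
#' `bf = 2 * (lnL_a - lnL_b)` on harmonic-mean log marginal likelihoods,
#' interpreted on the Kass-Raftery logarithmic scale: |bf| in (0, 2] is
#' barely worth mentioning, (2, 5] positive evidence, (5, 10] strong, and
#' above 10 very strong.
#'
#' @param lnL_a,lnL_b log marginal likelihoods of the two models.
#' @param names_ab optional character vector of length 2 naming the
#'   models.
#' @return An object of class `bayes_factor`: list with `bf`, `category`,
#'   `favored`, `lnL`.
#' @export
bayes_factor <- function(lnL_a, lnL_b, names_ab = c("model1", "model2")) {
  stopifnot(is.finite(lnL_a), is.finite(lnL_b))
  bf <- unname(2 * (lnL_a - lnL_b))
  structure(list(bf = bf,
                 category = bf_category(bf),
                 favored = if (bf >= 0) names_ab[1] else names_ab[2],
                 lnL = setNames(c(lnL_a, lnL_b), names_ab)),
            class = "bayes_factor")
}

#' @rdname bayes_factor
#' @param bf a Bayes factor on the 2 delta-lnL scale.
#' @export
bf_category <- function(bf) {
  a <- abs(bf)
  if (a <= 2) "barely worth mentioning"
  else if (a <= 5) "positive"
  else if (a <= 10) "strong"
  else "very strong"
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Bayes factor 2(lnL[%s] - lnL[%s]) = %.2f (%s; favors %s)\n",
              names(x$lnL)[1], names(x$lnL)[2], x$bf, x$category,
              x$favored))
  invisible(x)
}

#' Pairwise Bayes-factor table
#'
#' Entry (row r, column c) is `2 * (lnL[c] - lnL[r])`: positive values
#' support the column model, matching the sign convention of published
#' model-comparison tables.  The matrix is antisymmetric.
#'
#' @param lnL named numeric vector of log marginal likelihoods (>= 2
#'   models).
#' @return A square numeric matrix with model names on both dimensions.
#' @export
bf_table <- function(lnL) {
  if (length(lnL) < 2) stop("need at least two models")
  if (is.null(names(lnL))) names(lnL) <- paste0("m", seq_along(lnL))
  out <- outer(lnL, lnL, function(r, c) 2 * (c - r))
  dimnames(out) <- list(model_row = names(lnL), model_col = names(lnL))
  out
}
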