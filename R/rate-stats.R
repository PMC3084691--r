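#' Per-character maximum-likelihood transition rates
#'
#' Fits, for each character separately, the symmetric two-state model on
#' a fixed tree by maximising the likelihood over the transition rate in
#' `[lower, upper]` (changes per unit branch length).  Optimisation runs
#' in log-rate space with Brent's combined golden-section/parabolic
#' search, which is robust for the flat likelihood surfaces of
#' near-invariant characters.  Invariant characters have their maximum at
#' rate 0 and return the lower bound, flagged.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param m a [character_matrix()], or a named 0/1 vector for a single
#'   character.
#' @param lower,upper rate bounds (defaults 1e-8 and 100).
#' @param tol relative tolerance of the optimiser.
#' @return A data frame with one row per character: `character`, `rate`,
#'   `lnL`, `bound_hit` (`"lower"`, `"upper"` or `"none"`) and
#'   `converged`.
#' @export
ml_rate <- function(tree, m, lower = 1e-8, upper = 100, tol = 1e-7,
                    n_grid = 60) {
  if (!inherits(m, "character_matrix")) {
    m <- character_matrix(matrix(as.integer(m), ncol = 1,
                                 dimnames = list(names(m), "char")))
  }
  taxa <- rownames(m$states)
  tp <- .tree_post(tree, taxa)
  ws <- .make_ws(m$states, taxa)
  comp1 <- data.frame(rate = 1, pi1 = 0.5, weight = 1)
  ## coarse global scan (vectorised over site patterns), then local
  ## Brent refinement per pattern: the per-character likelihood in the
  ## rate can be bimodal (a finite mode plus a saturation mode), so a
  ## pure line search is unsafe
  lgrid <- seq(log(lower), log(upper), length.out = n_grid)
  gll <- vapply(lgrid, function(lr)
    log(.pattern_lik_component(tp$post, tp$elen * exp(lr), ws, 0.5, 1)),
    numeric(ws$npat))
  if (ws$npat == 1) gll <- matrix(gll, nrow = 1)
  pat_fit <- t(vapply(seq_len(ws$npat), function(i) {
    y <- ws$pat[, i]
    if (length(unique(y[!is.na(y)])) <= 1)
      return(c(rate = lower, lnL = gll[i, 1], bound = 1))
    k <- which.max(gll[i, ])
    lo <- lgrid[max(1, k - 1)]; hi <- lgrid[min(n_grid, k + 1)]
    f <- function(lr)
      log(.pattern_lik_component(tp$post, tp$elen * exp(lr),
                                 .ws_single(ws, i), 0.5, 1))
    o <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    r <- exp(o$maximum)
    bound <- if (r < lower * 1.01) 1 else if (r > upper * 0.99) 2 else 0
    c(rate = r, lnL = o$objective, bound = bound)
  }, numeric(3)))
  res <- pat_fit[ws$map, , drop = FALSE]
  data.frame(character = colnames(m$states),
             partition = unname(m$partition),
             rate = res[, "rate"], lnL = res[, "lnL"],
             bound_hit = c("none", "lower", "upper")[res[, "bound"] + 1],
             converged = TRUE,
             row.names = NULL, stringsAsFactors = FALSE)
}

## single-pattern view of a workspace (pattern i, plus the zero column)
.ws_single <- function(ws, i) {
  list(n = ws$n, taxa = ws$taxa, npat = 1L,
       pat = ws$pat[, i, drop = FALSE], w = 1, map = 1L,
       zero = NA_integer_, T0 = ws$T0[, i, drop = FALSE],
       T1 = ws$T1[, i, drop = FALSE])
}

#' Mann-Whitney U test (two-sided)
#'
#' U computed from rank sums with midranks for ties; the p-value comes
#' from exact enumeration of all arrangements when `length(x) +
#' length(y) <= exact_max`, otherwise from the normal approximation with
#' the tie correction.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max maximum combined sample size for exact enumeration
#'   (default 12).
#' @return List with `U` (statistic for the first sample), `p`
#'   (two-sided) and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("empty group")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_max) {
    idx <- combn(nx + ny, nx)
    Us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)   # continuity correction
  list(U = U, p = min(1, 2 * pnorm(-max(z, 0))), method = "normal")
}

#' Variance-difference tests between two rate samples
#'
#' Two-sided F test on the ratio of variances (numerator df from `x`)
#' and the nonparametric Fligner-Killeen test (normal scores on
#' median-centred absolute values, chi-squared on 1 df), the pair of
#' checks used to ask whether horizontal transfer inflates rate
#' variance without moving its centre.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return List with `F_ratio`, `F_p`, `df`, `fk_stat`, `fk_p`.
#' @export
variance_tests <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(y) == 0) stop("zero variance in denominator group")
  ft <- var.test(x, y)
  fk <- fligner.test(list(x, y))
  list(F_ratio = unname(ft$estimate), F_p = ft$p.value,
       df = unname(ft$parameter),
       fk_stat = unname(fk$statistic), fk_p = fk$p.value)
}

#' Compare rate distributions across partitions
#'
#' One-stop report of the distributional comparisons: medians and means
#' per group, Mann-Whitney U, F variance ratio, and Fligner-Killeen.
#'
#' @param rates numeric vector of per-character rates.
#' @param group vector of group labels parallel to `rates` (exactly two
#'   groups).
#' @return An object of class `rate_comparison` (a list; see fields in
#'   the examples), printable and convertible with `as.data.frame()`.
#' @export
summarize_rates <- function(rates, group) {
  g <- split(rates, group)
  if (length(g) != 2) stop("exactly two groups expected")
  x <- g[[1]]; y <- g[[2]]
  u <- mann_whitney_u(x, y)
  v <- variance_tests(x, y)
  structure(list(groups = names(g),
                 n = lengths(g),
                 median = vapply(g, median, numeric(1)),
                 mean = vapply(g, mean, numeric(1)),
                 U = u$U, U_p = u$p,
                 F_ratio = v$F_ratio, F_p = v$F_p, F_df = v$df,
                 fk_stat = v$fk_stat, fk_p = v$fk_p),
            class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("rate comparison: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  cat(sprintf("  medians %.4g vs %.4g; means %.4g vs %.4g\n",
              x$median[1], x$median[2], x$mean[1], x$mean[2]))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n", x$U, x$U_p))
  cat(sprintf("  F ratio = %.3g (df %d, %d), p = %.3g\n",
              x$F_ratio, x$F_df[1], x$F_df[2], x$F_p))
  cat(sprintf("  Fligner-Killeen chi^2 = %.3g, p = %.3g\n",
              x$fk_stat, x$fk_p))
  invisible(x)
}

#' @export
as.data.frame.rate_comparison <- function(x, ...) {
  data.frame(group = x$groups, n = x$n, median = x$median, mean = x$mean,
             U = x$U, U_p = x$U_p, F_ratio = x$F_ratio, F_p = x$F_p,
             fk_stat = x$fk_stat, fk_p = x$fk_p, row.names = NULL)
}
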