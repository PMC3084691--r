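#' Model specification for binary character evolution
#'
#' Describes the structure of the evolutionary model; numeric parameter
#' values (gamma shape, asymmetry concentration, partition rate
#' multipliers) live in a separate `params` list so that the MCMC can
#' update them without touching the specification.
#'
#' Rate asymmetry follows the standard-datatype convention for
#' morphological characters: instead of one shared stationary frequency,
#' the frequency of state 1 is drawn per character from a symmetric
#' Beta(alpha, alpha), discretised into `n_beta_cat` equal-weight
#' categories represented by their means.  Among-character rate variation
#' uses the usual discrete-gamma approximation with `n_gamma_cat`
#' equal-probability categories at their category means.  The
#' `no_absence_sites` ascertainment correction conditions each character's
#' likelihood on not being absent in every taxon, matching how
#' observational presence/absence matrices are assembled.
#'
#' @param asymmetry `"symmetric"` (stationary frequencies fixed at 1/2) or
#'   `"beta"` (Beta-mixture asymmetric frequencies).
#' @param gamma logical; gamma rate heterogeneity across characters.
#' @param ascertainment `"none"` or `"no_absence_sites"`.
#' @param partition_rates `"linked"` (one rate for all partitions) or
#'   `"unlinked"` (per-partition rate multipliers constrained to
#'   character-weighted mean 1).
#' @param topology `"linked"` (one tree) or `"unlinked"` (one tree per
#'   partition).
#' @param n_gamma_cat number of discrete gamma categories (default 4).
#' @param n_beta_cat number of discrete Beta categories (default 5).
#' @param gamma_shape,beta_alpha default parameter values used when a
#'   `params` list does not supply them.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(asymmetry = c("symmetric", "beta"),
                       gamma = FALSE,
                       ascertainment = c("none", "no_absence_sites"),
                       partition_rates = c("linked", "unlinked"),
                       topology = c("linked", "unlinked"),
                       n_gamma_cat = 4L, n_beta_cat = 5L,
                       gamma_shape = 1, beta_alpha = 1) {
  stopifnot(n_gamma_cat >= 1, n_beta_cat >= 1,
            gamma_shape > 0, beta_alpha > 0)
  structure(list(asymmetry = match.arg(asymmetry),
                 gamma = isTRUE(gamma),
                 ascertainment = match.arg(ascertainment),
                 partition_rates = match.arg(partition_rates),
                 topology = match.arg(topology),
                 n_gamma_cat = as.integer(n_gamma_cat),
                 n_beta_cat = as.integer(n_beta_cat),
                 gamma_shape = gamma_shape, beta_alpha = beta_alpha),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(paste0("model_spec: %s rates%s, ascertainment=%s, ",
                     "partition rates %s, topology %s\n"),
              x$asymmetry,
              if (x$gamma) sprintf(" + gamma(%d cat)", x$n_gamma_cat) else "",
              x$ascertainment, x$partition_rates, x$topology))
  invisible(x)
}

#' Transition probability matrix for a binary character
#'
#' Two-state continuous-time chain with stationary frequencies
#' `(1 - pi1, pi1)`, normalised so that one unit of branch length equals
#' one expected state change at stationarity:
#' `P_ij(t) = pi_j + (delta_ij - pi_j) * exp(-beta * t)` with
#' `beta = 1 / (2 * pi0 * pi1)`.
#'
#' @param pi1 stationary frequency of state 1, in (0, 1).
#' @param t branch length times rate multiplier, >= 0.
#' @return A 2x2 matrix; rows are the starting state (0, 1), columns the
#'   ending state; rows sum to 1.
#' @export
transition_prob <- function(pi1, t) {
  stopifnot(pi1 > 0, pi1 < 1)
  if (t < 0) stop("negative branch length")
  pi0 <- 1 - pi1
  e <- exp(-t / (2 * pi0 * pi1))
  matrix(c(pi0 + pi1 * e, pi0 - pi0 * e,
           pi1 - pi1 * e, pi1 + pi0 * e),
         2, 2, dimnames = list(from = c("0", "1"), to = c("0", "1")))
}

#' Discrete-gamma category rates
#'
#' Mean-of-category representation of a Gamma(shape, shape) distribution
#' (mean 1) cut into `k` equal-probability categories.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories.
#' @return Numeric vector of `k` rates averaging 1.
#' @export
gamma_category_rates <- function(shape, k) {
  if (k == 1) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
  k * diff(pgamma(q, shape + 1, rate = shape))
}

#' Discrete-Beta category frequencies
#'
#' Mean-of-category representation of a symmetric Beta(alpha, alpha) over
#' the stationary frequency of state 1, cut into `k` equal-probability
#' categories; the mixture is symmetric around 1/2.
#'
#' @param alpha Beta concentration (> 0).
#' @param k number of categories.
#' @return Numeric vector of `k` frequencies in (0, 1) averaging 1/2.
#' @export
beta_category_freqs <- function(alpha, k) {
  if (k == 1) return(0.5)
  q <- qbeta(seq(0, 1, length.out = k + 1), alpha, alpha)
  f <- k * 0.5 * diff(pbeta(q, alpha + 1, alpha))
  pmin(pmax(f, 1e-12), 1 - 1e-12)
}

## mixture components implied by a spec + params:
## data.frame(rate, pi1, weight), weights summing to 1
.model_components <- function(spec, params = list()) {
  shape <- params$gamma_shape %||% spec$gamma_shape
  alpha <- params$beta_alpha %||% spec$beta_alpha
  rates <- if (spec$gamma) gamma_category_rates(shape, spec$n_gamma_cat) else 1
  freqs <- if (spec$asymmetry == "beta")
    beta_category_freqs(alpha, spec$n_beta_cat) else 0.5
  comp <- expand.grid(rate = rates, pi1 = freqs)
  comp$weight <- 1 / nrow(comp)
  comp
}

## ---------------------------------------------------------------------
## pruning engine
## ---------------------------------------------------------------------

## Prepare a likelihood workspace for a fixed character block:
## compressed site patterns + bookkeeping.  `x` is an n_taxa x n_char
## 0/1/NA matrix with row names; taxa order inside the workspace follows
## `taxa`.
.make_ws <- function(x, taxa = rownames(x)) {
  x <- x[taxa, , drop = FALSE]
  n <- length(taxa)
  if (ncol(x) == 0)
    return(list(n = n, taxa = taxa, npat = 0L,
                pat = matrix(NA_integer_, n, 0), w = numeric(0),
                map = integer(0), zero = NA_integer_,
                T0 = matrix(1, n, 0), T1 = matrix(1, n, 0)))
  key <- apply(x, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  map <- match(key, key[u])
  pat <- x[, u, drop = FALSE]
  w <- as.numeric(tabulate(map, nbins = sum(u)))
  ## append the all-absent pattern (weight 0) so one pruning pass also
  ## yields the ascertainment-correction term
  zkey <- paste(rep(0L, n), collapse = "\r")
  zero <- match(zkey, key[u])
  if (is.na(zero)) {
    pat <- cbind(pat, 0L)
    w <- c(w, 0)
    zero <- ncol(pat)
  }
  ## precomputed tip partial likelihoods (missing data: both states 1)
  T0 <- ifelse(is.na(pat), 1, (pat == 0L) * 1)
  T1 <- ifelse(is.na(pat), 1, (pat == 1L) * 1)
  list(n = n, taxa = taxa, npat = ncol(pat), pat = pat, w = w, map = map,
       zero = zero, T0 = T0, T1 = T1)
}

## Per-pattern likelihood vector under one mixture component, by pruning.
## `post` = postorder edge matrix (parent, child) with node numbering
## 1..n tips then internals, root = n+1; `elen` = branch length per edge
## row (already multiplied by any rate multiplier).
.pattern_lik_component <- function(post, elen, ws, pi1, rate) {
  n <- ws$n; npat <- ws$npat
  if (npat == 0) return(numeric(0))
  nn <- max(post)
  pi0 <- 1 - pi1
  beta <- 1 / (2 * pi0 * pi1)
  L0 <- matrix(1, nn, npat); L1 <- matrix(1, nn, npat)
  L0[seq_len(n), ] <- ws$T0
  L1[seq_len(n), ] <- ws$T1
  e <- exp(-beta * rate * elen)
  P00 <- pi0 + pi1 * e; P01 <- pi1 - pi1 * e
  P10 <- pi0 - pi0 * e; P11 <- pi1 + pi0 * e
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1]; ch <- post[k, 2]
    l0 <- L0[ch, ]; l1 <- L1[ch, ]
    L0[p, ] <- L0[p, ] * (P00[k] * l0 + P01[k] * l1)
    L1[p, ] <- L1[p, ] * (P10[k] * l0 + P11[k] * l1)
  }
  root <- post[nrow(post), 1]
  pi0 * L0[root, ] + pi1 * L1[root, ]
}

## Sum of per-character log likelihoods for one character block on one
## tree.  Returns the total; with `per_pattern = TRUE` also the mixture
## likelihood per compressed pattern (used by posterior_site_rates).
## The ascertainment term uses the all-absent pattern carried by the
## workspace (weight 0), so a single pruning pass per component covers
## both.
.block_loglik <- function(post, elen, ws, comps, ascertain,
                          per_pattern = FALSE) {
  if (ws$npat == 0)
    return(if (per_pattern) list(total = 0, lmix = numeric(0)) else 0)
  lmix <- numeric(ws$npat)
  for (j in seq_len(nrow(comps))) {
    lmix <- lmix + comps$weight[j] *
      .pattern_lik_component(post, elen, ws, comps$pi1[j], comps$rate[j])
  }
  lc <- if (ascertain) lmix / (1 - lmix[ws$zero]) else lmix
  total <- sum(ws$w * log(lc))
  if (per_pattern) list(total = total, lmix = lc) else total
}

## postorder edges + lengths from an ape tree, tips ordered as `taxa`
.tree_post <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa))
    stop("tree taxa do not match the character matrix")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length in tree")
  perm <- match(tree$tip.label, taxa)
  tr2 <- stats::reorder(tree, "postorder")
  edge <- tr2$edge
  n <- length(taxa)
  relab <- c(perm, seq(n + 1L, n + tree$Nnode))
  edge[] <- relab[edge]
  list(post = edge, elen = tr2$edge.length)
}

#' Log-likelihood of one character on a tree
#'
#' Felsenstein pruning over the model's mixture components (gamma rate
#' categories and Beta asymmetry categories, equal weights, category
#' means), with the root weighted by the component's stationary
#' frequencies.  Under the `no_absence_sites` correction the returned
#' value is `log L - log(1 - L_all_absent)`, where both terms are mixture
#' likelihoods on the same tree and parameters.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param states named 0/1/`NA` vector, one entry per taxon.
#' @param spec a [model_spec()].
#' @param params optional list with `gamma_shape`, `beta_alpha`, and
#'   `rate` (a branch-length multiplier, default 1).
#' @return The log-likelihood (a scalar).
#' @export
character_loglik <- function(tree, states, spec = model_spec(),
                             params = list()) {
  taxa <- names(states)
  if (is.null(taxa)) stop("`states` must be named by taxon")
  x <- matrix(as.integer(states), ncol = 1,
              dimnames = list(taxa, "char"))
  ws <- .make_ws(x, taxa)
  tp <- .tree_post(tree, taxa)
  mult <- params$rate %||% 1
  comps <- .model_components(spec, params)
  .block_loglik(tp$post, tp$elen * mult, ws, comps,
                spec$ascertainment == "no_absence_sites")
}

#' Brute-force log-likelihood by enumeration over internal states
#'
#' Independent oracle for [character_loglik()]: sums, over every
#' assignment of states to internal nodes, the product of the root's
#' stationary frequency and the per-edge transition probabilities, mixed
#' over model components and ascertainment-corrected exactly as the
#' pruning engine.  Limited to small trees.
#'
#' @inheritParams character_loglik
#' @param max_taxa refuse larger trees (default 6; enumeration is
#'   exponential).
#' @return The log-likelihood (a scalar).
#' @export
brute_force_loglik <- function(tree, states, spec = model_spec(),
                               params = list(), max_taxa = 6) {
  taxa <- names(states)
  if (length(taxa) > max_taxa)
    stop("too many taxa for brute-force enumeration")
  tp <- .tree_post(tree, taxa)
  mult <- params$rate %||% 1
  elen <- tp$elen * mult
  comps <- .model_components(spec, params)
  n <- length(taxa)
  nint <- tree$Nnode
  lik_pattern <- function(y, pi1, rate) {
    pi0 <- 1 - pi1
    beta <- 1 / (2 * pi0 * pi1)
    total <- 0
    for (a in seq_len(2^nint) - 1L) {
      sint <- as.integer(intToBits(a))[seq_len(nint)]
      s <- c(y, sint)
      pr <- if (s[n + 1L] == 1L) pi1 else pi0
      for (k in seq_len(nrow(tp$post))) {
        i <- s[tp$post[k, 1]]; j <- s[tp$post[k, 2]]
        if (is.na(j)) next  # missing tip: partial likelihood 1
        e <- exp(-beta * rate * elen[k])
        pij <- if (i == j) (if (j == 1L) pi1 + pi0 * e else pi0 + pi1 * e)
               else        (if (j == 1L) pi1 - pi1 * e else pi0 - pi0 * e)
        pr <- pr * pij
      }
      total <- total + pr
    }
    total
  }
  y <- as.integer(states)
  lmix <- 0; l0 <- 0
  for (jj in seq_len(nrow(comps))) {
    lmix <- lmix + comps$weight[jj] *
      lik_pattern(y, comps$pi1[jj], comps$rate[jj])
    if (spec$ascertainment == "no_absence_sites")
      l0 <- l0 + comps$weight[jj] *
        lik_pattern(rep(0L, n), comps$pi1[jj], comps$rate[jj])
  }
  if (spec$ascertainment == "no_absence_sites")
    log(lmix) - log(1 - l0) else log(lmix)
}

#' Total log-likelihood of a character matrix
#'
#' Sums [character_loglik()] over all characters, evaluating each
#' character on its partition's tree (when topologies are unlinked) and
#' with its partition's rate multiplier (when partition rates are
#' unlinked).  Site patterns are compressed per partition, so repeated
#' patterns cost one pruning pass.
#'
#' @param trees a single rooted `ape::phylo`, or (for unlinked
#'   topologies) a named list of trees, one per partition label.
#' @param m a [character_matrix()].
#' @param spec a [model_spec()].
#' @param params optional list with `gamma_shape`, `beta_alpha`, and
#'   `rate_multipliers` (named per partition; default all 1).
#' @param per_character logical; also return the per-character log
#'   likelihoods.
#' @return The total log-likelihood, or (with `per_character = TRUE`) a
#'   list with `total` and `per_character` (named by character).
#' @export
matrix_loglik <- function(trees, m, spec = model_spec(), params = list(),
                          per_character = FALSE) {
  stopifnot(inherits(m, "character_matrix"))
  taxa <- rownames(m$states)
  labs <- unique(m$partition)
  if (inherits(trees, "phylo")) {
    trees <- setNames(rep(list(trees), length(labs)), labs)
  } else {
    miss <- setdiff(labs, names(trees))
    if (length(miss)) stop("no tree supplied for partition: ", miss[1])
  }
  mult <- params$rate_multipliers %||% setNames(rep(1, length(labs)), labs)
  comps <- .model_components(spec, params)
  ascertain <- spec$ascertainment == "no_absence_sites"
  total <- 0
  perchar <- setNames(numeric(ncol(m$states)), colnames(m$states))
  for (l in labs) {
    sel <- m$partition == l
    ws <- .make_ws(m$states[, sel, drop = FALSE], taxa)
    tp <- .tree_post(trees[[l]], taxa)
    res <- .block_loglik(tp$post, tp$elen * (mult[[l]] %||% 1), ws, comps,
                         ascertain, per_pattern = per_character)
    if (per_character) {
      perchar[sel] <- log(res$lmix)[ws$map]
      total <- total + res$total
    } else total <- total + res
  }
  if (per_character) list(total = total, per_character = perchar) else total
}

#' Posterior mean relative rate per character
#'
#' Under the gamma model every character has, at each sampled generation,
#' a conditional distribution over the gamma rate categories proportional
#' to the category's prior weight times the character's likelihood in
#' that category.  The per-character posterior relative rate is the
#' conditional expectation of the category rate, averaged over the
#' posterior sample.  With gamma off all rates are exactly 1 by contract.
#'
#' @param posterior a `posterior_sample` from [run_mcmc()] (or
#'   [pool_runs()]).
#' @param m the [character_matrix()] the posterior was sampled for.
#' @param spec the [model_spec()] used.
#' @return Named numeric vector of posterior mean relative rates, one per
#'   character.
#' @export
posterior_site_rates <- function(posterior, m, spec) {
  cn <- colnames(m$states)
  if (!spec$gamma)
    return(setNames(rep(1, length(cn)), cn))
  taxa <- rownames(m$states)
  labs <- unique(m$partition)
  wss <- lapply(labs, function(l)
    .make_ws(m$states[, m$partition == l, drop = FALSE], taxa))
  names(wss) <- labs
  acc <- setNames(rep(0, length(cn)), cn)
  ns <- nrow(posterior$samples)
  for (s in seq_len(ns)) {
    shape <- posterior$samples$gamma_shape[s] %||% spec$gamma_shape
    grates <- gamma_category_rates(shape, spec$n_gamma_cat)
    freqs <- if (spec$asymmetry == "beta")
      beta_category_freqs(posterior$samples$beta_alpha[s] %||%
                            spec$beta_alpha, spec$n_beta_cat) else 0.5
    for (l in labs) {
      sel <- m$partition == l
      tree <- posterior$trees[[.tree_key(posterior, l)]][[s]]
      tp <- .tree_post(tree, taxa)
      mcol <- paste0("mult_", l)
      mlt <- if (mcol %in% names(posterior$samples))
        posterior$samples[[mcol]][s] else 1
      ws <- wss[[l]]
      lg <- matrix(0, length(grates), ws$npat)
      for (gi in seq_along(grates)) for (f in freqs) {
        lg[gi, ] <- lg[gi, ] + (1 / length(freqs)) *
          .pattern_lik_component(tp$post, tp$elen * mlt, ws, f, grates[gi])
      }
      rhat <- colSums(lg * grates) / colSums(lg)
      acc[sel] <- acc[sel] + rhat[ws$map]
    }
  }
  acc / ns
}

## partition label -> tree list key ("tree" when topologies are linked)
.tree_key <- function(posterior, label) {
  if (label %in% names(posterior$trees)) label else names(posterior$trees)[1]
}
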