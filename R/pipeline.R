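#' Model exploration: fit the four-model grid and pick a base model
#'
#' Fits the grid {symmetric (S), symmetric + gamma (SG), asymmetric (A),
#' asymmetric + gamma (AG)} by MCMC, estimates each model's harmonic-mean
#' log marginal likelihood from the pooled post-burn-in sample, and
#' reports the full pairwise Bayes-factor table; the argmax model is
#' named the base model.
#'
#' @param m a [character_matrix()].
#' @param cfg an [mcmc_config()].
#' @param ascertainment passed to every [model_spec()].
#' @return List with `table1` (data frame: model, lnL), `table2` (the
#'   [bf_table()] matrix), `base_model`, `posteriors` (named list of
#'   `posterior_sample`s).
#' @export
run_model_exploration <- function(m, cfg = mcmc_config(),
                                  ascertainment = "no_absence_sites") {
  grid <- list(
    S  = model_spec("symmetric", gamma = FALSE, ascertainment = ascertainment),
    SG = model_spec("symmetric", gamma = TRUE,  ascertainment = ascertainment),
    A  = model_spec("beta",      gamma = FALSE, ascertainment = ascertainment),
    AG = model_spec("beta",      gamma = TRUE,  ascertainment = ascertainment))
  posteriors <- lapply(grid, function(sp) run_mcmc(m, sp, cfg))
  lnL <- vapply(posteriors, function(p)
    harmonic_mean_lnL(p$samples$lnL), numeric(1))
  base <- names(lnL)[which.max(lnL)]
  list(table1 = data.frame(model = names(lnL), lnL = unname(lnL)),
       table2 = bf_table(lnL),
       base_model = base,
       posteriors = posteriors)
}

#' Partition-rate test (core-versus-peripheral rates)
#'
#' Compares the base model against the same model with the partition
#' rate parameter unlinked (each partition gets its own branch-length
#' multiplier, character-weighted mean 1) by harmonic-mean Bayes factor.
#' Additionally runs the gamma model, extracts the per-character
#' posterior relative rates, and compares them between the two
#' partitions (Mann-Whitney U, F ratio, Fligner-Killeen).
#'
#' @param m a [character_matrix()] with at least two partitions.
#' @param cfg an [mcmc_config()].
#' @param base_spec the base model's [model_spec()].
#' @return List with `bf` (a [bayes_factor()]; positive favours the
#'   rate-unlinked model), `rate_report` (a `rate_comparison`),
#'   `site_rates`, and the two posteriors.
#' @export
run_rate_partition_test <- function(m, cfg = mcmc_config(),
                                    base_spec = model_spec(
                                      ascertainment = "no_absence_sites")) {
  labs <- unique(m$partition)
  if (length(labs) < 2) stop("need >= 2 partitions")
  unlinked_spec <- base_spec
  unlinked_spec$partition_rates <- "unlinked"
  post_base <- run_mcmc(m, base_spec, cfg)
  post_unl <- run_mcmc(m, unlinked_spec, cfg)
  bf <- bayes_factor(harmonic_mean_lnL(post_unl$samples$lnL),
                     harmonic_mean_lnL(post_base$samples$lnL),
                     c("rates_unlinked", "base"))
  gamma_spec <- base_spec
  gamma_spec$gamma <- TRUE
  post_gamma <- run_mcmc(m, gamma_spec, cfg)
  rates <- posterior_site_rates(post_gamma, m, gamma_spec)
  report <- summarize_rates(rates, m$partition)
  list(bf = bf, rate_report = report, site_rates = rates,
       posterior_base = post_base, posterior_unlinked = post_unl,
       posterior_gamma = post_gamma)
}

#' Topology-unlinking test (many coherent units)
#'
#' Compares the single-tree base model with the topology-unlinked model
#' (an independent tree per partition) by harmonic-mean Bayes factor and
#' returns per-partition majority-rule consensus trees with clade
#' credibilities.
#'
#' @param m a [character_matrix()] with two partitions (more are
#'   accepted; trees are reported per partition).
#' @param cfg an [mcmc_config()].
#' @param base_spec the base model's [model_spec()].
#' @return List with `bf` (positive favours unlinked topologies),
#'   `consensus` (named list of [majority_consensus()] results per
#'   partition) and the two posteriors.
#' @export
run_topology_unlink_test <- function(m, cfg = mcmc_config(),
                                     base_spec = model_spec(
                                       ascertainment = "no_absence_sites")) {
  labs <- unique(m$partition)
  if (length(labs) < 2) stop("need >= 2 partitions")
  unl_spec <- base_spec
  unl_spec$topology <- "unlinked"
  post_base <- run_mcmc(m, base_spec, cfg)
  post_unl <- run_mcmc(m, unl_spec, cfg)
  bf <- bayes_factor(harmonic_mean_lnL(post_unl$samples$lnL),
                     harmonic_mean_lnL(post_base$samples$lnL),
                     c("topology_unlinked", "base"))
  consensus <- lapply(post_unl$trees, majority_consensus)
  list(bf = bf, consensus = consensus,
       posterior_base = post_base, posterior_unlinked = post_unl)
}

#' Constrained-topology comparison
#'
#' Harmonic-mean Bayes factor of an unconstrained run against a run in
#' which a clade is enforced to be monophyletic (the constraint used in
#' the study forces Papi sister to Bakhtiari in the pile-character
#' tree).  A positive Bayes factor favours the unconstrained topology.
#'
#' @param m a [character_matrix()].
#' @param clade character vector of taxa to constrain.
#' @param cfg an [mcmc_config()].
#' @param spec the [model_spec()] for both runs.
#' @return List with `bf` and the two posteriors.
#' @export
run_constrained_comparison <- function(m, clade, cfg = mcmc_config(),
                                       spec = model_spec(
                                         ascertainment = "no_absence_sites")) {
  if (!all(clade %in% rownames(m$states)))
    stop("constraint clade not a subset of the taxa")
  cfg_con <- cfg
  cfg_con$constraint <- clade
  post_free <- run_mcmc(m, spec, cfg)
  post_con <- run_mcmc(m, spec, cfg_con)
  bf <- bayes_factor(harmonic_mean_lnL(post_free$samples$lnL),
                     harmonic_mean_lnL(post_con$samples$lnL),
                     c("unconstrained", "constrained"))
  list(bf = bf, posterior_free = post_free, posterior_constrained = post_con)
}

#' Horizontal-transfer rate-bias simulation study
#'
#' The study's simulation experiment: simulate a no-transfer baseline of
#' `n_baseline` characters at the generating rate on the Grafen
#' reference tree, then `n_sets` sets of `set_size` characters per
#' borrowing regime; overlay tip-level transfers, drop invariant
#' characters from the transfer sets (the baseline keeps all
#' characters), estimate every character's symmetric ML transition rate
#' on the same tree, and report per regime the percentage of sets whose
#' median rate exceeds the no-transfer median.
#'
#' @param tree simulation/estimation tree (default the Grafen-transformed
#'   7-taxon reference tree; borrowing is restricted to the ingroup
#'   tribes).
#' @param eligible taxa allowed to borrow and donate.
#' @param rate generating transition rate.
#' @param n_baseline baseline characters (no transfer, no filtering).
#' @param n_sets transfer sets per regime.
#' @param set_size characters per transfer set.
#' @param adopt_prob per-taxon per-character adoption probability.
#' @param modes borrowing regimes to run.
#' @param seed RNG seed (single integer).
#' @return List with `baseline` (median, mean, rates), `modes` (named
#'   list: percent_above, set_medians, retained counts) and the
#'   configuration.
#' @export
run_transfer_rate_study <- function(tree = textile_reference_tree(),
                                    eligible = textile_tribes(),
                                    rate = 0.123, n_baseline = 100,
                                    n_sets = 100, set_size = 30,
                                    adopt_prob = 0.30,
                                    modes = c("local", "antilocal",
                                              "global"),
                                    seed = 1) {
  set.seed(seed)
  eligible <- intersect(eligible, tree$tip.label)
  base <- simulate_characters(tree, rate, n_baseline,
                              partition_label = "baseline")
  base_fit <- ml_rate(tree, base)
  base_median <- median(base_fit$rate)
  base_mean <- mean(base_fit$rate)
  out_modes <- list()
  for (mode in modes) {
    cfgt <- transfer_config(mode, adopt_prob)
    donors <- transfer_donor_sets(tree, mode, eligible)
    if (any(lengths(donors) == 0))
      message("note: no ", mode, " donors for ",
              paste(names(donors)[lengths(donors) == 0], collapse = ", "))
    meds <- numeric(n_sets); kept <- integer(n_sets)
    for (s in seq_len(n_sets)) {
      mm <- simulate_characters(tree, rate, set_size,
                                partition_label = mode)
      mm <- suppressWarnings(apply_transfers(mm, tree, cfgt,
                                             eligible = eligible))
      mm <- drop_invariant(mm)
      kept[s] <- ncol(mm$states)
      meds[s] <- median(ml_rate(tree, mm)$rate)
    }
    out_modes[[mode]] <- list(percent_above = 100 * mean(meds > base_median),
                              set_medians = meds, retained = kept)
  }
  structure(list(baseline = list(median = base_median, mean = base_mean,
                                 rates = base_fit$rate),
                 modes = out_modes,
                 config = list(rate = rate, n_baseline = n_baseline,
                               n_sets = n_sets, set_size = set_size,
                               adopt_prob = adopt_prob, seed = seed,
                               eligible = eligible)),
            class = "transfer_rate_study")
}

#' @export
print.transfer_rate_study <- function(x, ...) {
  cat(sprintf(paste0("transfer-rate study: %d baseline characters ",
                     "(median rate %.3f, mean %.2f)\n"),
              x$config$n_baseline, x$baseline$median, x$baseline$mean))
  for (mode in names(x$modes)) {
    mo <- x$modes[[mode]]
    cat(sprintf("  %-9s %5.1f%% of %d sets above baseline median; ",
                mode, mo$percent_above, length(mo$set_medians)))
    cat(sprintf("retained %d-%d of %d characters\n", min(mo$retained),
                max(mo$retained), x$config$set_size))
  }
  invisible(x)
}
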