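#!/usr/bin/env Rscript
## Topology-unlinking test (many coherent units prediction).
##
## Generates one congruent dataset (both partitions on the reference
## tree) and one incongruent dataset (pile partition evolved on the
## Papi-shifted tree), fits the single-tree base model and the
## topology-unlinked model to each, and reports the Bayes factors plus
## per-partition consensus trees with clade credibilities.

suppressMessages(library(coherentunits))
dir.create("results", showWarnings = FALSE)

cfg <- mcmc_config(n_generations = 24000, sample_every = 20, n_runs = 1,
                   n_chains = 2, retain = 800, seed = 4)

run_case <- function(label, trees) {
  set.seed(4)
  m <- make_textile_like_dataset(trees = trees,
                                 n_chars = c(nonpile = 98, pile = 24))
  res <- suppressWarnings(run_topology_unlink_test(m, cfg))
  cat("==", label, "dataset\n")
  print(res$bf)
  for (p in names(res$consensus)) {
    nwk <- write_newick(res$consensus[[p]]$tree)
    cat(sprintf("  %s consensus: %s\n", p, nwk))
    writeLines(nwk, sprintf("results/consensus_%s_%s.nwk", label, p))
  }
  data.frame(dataset = label, bf = res$bf$bf,
             category = res$bf$category, favored = res$bf$favored)
}

out <- rbind(
  run_case("congruent", list()),
  run_case("incongruent", list(pile = textile_reference_tree("pile"))))
cat("\n")
print(out, row.names = FALSE)
write.csv(out, "results/topology_unlink_test.csv", row.names = FALSE)
cat("Wrote results/topology_unlink_test.csv and consensus newicks\n")
cat("\nNote: at the study's generating rate the pile partition (24\n")
cat("characters) holds little topological information, so single-dataset\n")
cat("Bayes factors are noisy; the replicate behaviour is characterised\n")
cat("in the test suite.\n")
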