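#!/usr/bin/env Rscript
## Rate-partition test (hierarchically integrated system prediction).
##
## On a synthetic dataset with pile vs non-pile partitions sharing one
## history: compares the base model against the model with unlinked
## per-partition rate multipliers by Bayes factor, and contrasts the
## gamma model's per-character posterior rates between partitions
## (Mann-Whitney U, variance F, Fligner-Killeen).  Under this congruent,
## equal-rate null the expectation is no support for unlinked rates and
## calm distribution tests.

suppressMessages(library(coherentunits))
dir.create("results", showWarnings = FALSE)

set.seed(3)
m <- make_textile_like_dataset(n_chars = c(nonpile = 98, pile = 24))
cfg <- mcmc_config(n_generations = 16000, sample_every = 20, n_runs = 1,
                   n_chains = 2, retain = 550, seed = 3)

res <- suppressWarnings(run_rate_partition_test(m, cfg))

print(res$bf)
cat("\nPer-character posterior relative rates (gamma model):\n")
print(res$rate_report)

df <- as.data.frame(res$rate_report)
df$bf_rates_unlinked_vs_base <- res$bf$bf
write.csv(df, "results/rate_partition_test.csv", row.names = FALSE)
write.csv(data.frame(character = names(res$site_rates),
                     partition = m$partition,
                     posterior_rate = unname(res$site_rates)),
          "results/site_rates.csv", row.names = FALSE)
cat("\nWrote results/rate_partition_test.csv and results/site_rates.csv\n")
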