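test_that("configuration invariants are enforced", {
  expect_error(mcmc_config(n_generations = 1000, sample_every = 300),
               "divide")
  expect_error(mcmc_config(n_generations = 1000, sample_every = 100,
                           retain = 20), "retain")
  cfg <- mcmc_config(n_generations = 1000, sample_every = 100,
                     burnin_fraction = 0.1)
  expect_equal(cfg$retain, 9L)
})

test_that("burn-in detection keeps the final window and flags trends", {
  ## 1000 samples, default retention convention: cut 100, keep 900
  tr <- rnorm(1000)
  k <- detect_burnin(tr, retain = 900)
  expect_equal(k$cut, 100)
  expect_equal(k$retain, 900)

  set.seed(18)
  expect_silent(detect_burnin(rnorm(500, -100), retain = 400))
  expect_warning(detect_burnin(seq(-200, -100, length.out = 500),
                               retain = 400), "stationary")
  expect_error(detect_burnin(rnorm(10), retain = 900), "retain")
})

test_that("pooling runs concatenates with provenance and checks specs", {
  mk <- function(run, n, spec) {
    structure(list(samples = data.frame(run = run, generation = seq_len(n),
                                        lnL = rnorm(n)),
                   trees = list(tree = rep(list(tree_cherry4()), n)),
                   acceptance = c(nni = 0.5), spec = spec,
                   config = NULL), class = "posterior_sample")
  }
  sp <- model_spec()
  pooled <- pool_runs(lapply(1:6, mk, n = 900, spec = sp))
  expect_equal(nrow(pooled$samples), 5400)
  expect_equal(length(pooled$trees$tree), 5400)
  expect_equal(sort(unique(pooled$samples$run)), 1:6)

  single <- mk(1, 10, sp)
  expect_identical(pool_runs(single), single)
  expect_error(pool_runs(list(mk(1, 5, sp),
                              mk(2, 5, model_spec(gamma = TRUE)))),
               "specifications")
})

test_that("prior-only sampling recovers the prior marginals", {
  taxa <- c("A", "B", "C", "D")
  m0 <- character_matrix(matrix(integer(0), 4, 0,
                                dimnames = list(taxa, NULL)))
  cfg <- mcmc_config(n_generations = 30000, sample_every = 10, n_runs = 1,
                     n_chains = 1, retain = 2500, seed = 42)
  post <- suppressWarnings(run_mcmc(m0, model_spec(), cfg))
  ## topology marginal: uniform over the 15 rooted topologies
  keys <- vapply(post$trees[[1]], topo_key, character(1))
  freq <- table(keys) / length(keys)
  expect_equal(length(freq), 15L)
  expect_lt(max(abs(as.numeric(freq) - 1 / 15)), 0.03)
  ## branch-length marginal: exponential(mean 0.1)
  bl <- unlist(lapply(post$trees[[1]], function(t) t$edge.length))
  expect_equal(mean(bl), 0.1, tolerance = 0.05)
  expect_equal(var(bl), 0.01, tolerance = 0.1)
  ## prior run has zero likelihood everywhere
  expect_true(all(post$samples$lnL == 0))
})

test_that("constrained runs only visit constraint-satisfying trees", {
  set.seed(19)
  tr <- tree_cherry4()
  m <- simulate_characters(tr, 1, 10)
  cfg <- mcmc_config(n_generations = 2000, sample_every = 10, n_runs = 1,
                     n_chains = 2, retain = 150, seed = 20,
                     constraint = c("A", "B"))
  post <- suppressWarnings(run_mcmc(m, model_spec(), cfg))
  ok <- vapply(post$trees[[1]], check_constraint, logical(1),
               clade = c("A", "B"))
  expect_true(all(ok))
  expect_error(run_mcmc(m, model_spec(),
                        mcmc_config(n_generations = 100, sample_every = 10,
                                    retain = 5, constraint = c("A", "Z"))),
               "subset")
})

test_that("posterior topology frequencies match the analytic oracle", {
  set.seed(7)
  taxa <- c("A", "B", "C", "D")
  gen <- ape::read.tree(text = "((A:0.1,B:0.15):0.1,(C:0.05,D:0.2):0.12);")
  m <- simulate_characters(gen, rate = 2, n_chars = 5)
  topos <- rooted_topologies4(taxa)
  marg <- vapply(topos, function(tx) exact_marginal4(tx, m$states),
                 numeric(1))
  exact <- setNames(marg / sum(marg),
                    vapply(topos, function(tx)
                      topo_key(ape::read.tree(text = tx)), character(1)))
  cfg <- mcmc_config(n_generations = 30000, sample_every = 10, n_runs = 2,
                     n_chains = 2, retain = 2200, seed = 11)
  post <- suppressWarnings(run_mcmc(m, model_spec(), cfg))
  keys <- vapply(post$trees[[1]], topo_key, character(1))
  freq <- table(factor(keys, levels = names(exact))) / length(keys)
  expect_lt(max(abs(as.numeric(freq) - unname(exact))), 0.04)
})

test_that("clade credibilities converge across independent seeds", {
  set.seed(23)
  gen <- ape::read.tree(text = "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3);")
  m <- simulate_characters(gen, rate = 1, n_chars = 40)
  cred_ab <- vapply(c(101, 202), function(sd) {
    cfg <- mcmc_config(n_generations = 16000, sample_every = 10,
                       n_runs = 1, n_chains = 2, retain = 1100, seed = sd)
    post <- suppressWarnings(run_mcmc(m, model_spec(), cfg))
    mean(vapply(post$trees[[1]], check_constraint, logical(1),
                clade = c("A", "B")))
  }, numeric(1))
  expect_lt(abs(diff(cred_ab)), 0.03 + 0.02)
})

test_that("degenerate input (one variable character) yields a diffuse posterior", {
  taxa <- c("A", "B", "C", "D")
  s <- matrix(c(1L, 1L, 0L, 0L), 4, 1, dimnames = list(taxa, "only"))
  m <- character_matrix(s)
  cfg <- mcmc_config(n_generations = 8000, sample_every = 10, n_runs = 1,
                     n_chains = 1, retain = 600, seed = 5)
  post <- suppressWarnings(run_mcmc(m, model_spec(), cfg))
  keys <- vapply(post$trees[[1]], topo_key, character(1))
  expect_gt(length(unique(keys)), 5)
})
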