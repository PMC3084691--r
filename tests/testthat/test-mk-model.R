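test_that("transition probabilities: limits, closed form, Chapman-Kolmogorov", {
  expect_equal(transition_prob(0.5, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_prob(0.5, 1e9), matrix(0.5, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  ## pi1 = 0.5, t = 0.5: beta = 2, P01 = 0.5 (1 - e^-1)
  expect_equal(transition_prob(0.5, 0.5)[1, 2], 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_error(transition_prob(0.5, -1), "negative")

  set.seed(1)
  for (i in 1:25) {
    p1 <- runif(1, 0.05, 0.95)
    t1 <- rexp(1); t2 <- rexp(1)
    expect_equal(transition_prob(p1, t1) %*% transition_prob(p1, t2),
                 transition_prob(p1, t1 + t2),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(rowSums(transition_prob(p1, t1)), c(1, 1),
                 ignore_attr = TRUE, tolerance = 1e-14)
  }
})

test_that("two-taxon likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(A:0.4,B:0.7);")
  y <- c(A = 0L, B = 0L)
  P <- function(t) transition_prob(0.5, t)
  manual <- log(0.5 * P(0.4)[1, 1] * P(0.7)[1, 1] +
                0.5 * P(0.4)[2, 1] * P(0.7)[2, 1])
  expect_equal(character_loglik(tr, y), manual, tolerance = 1e-12)
  expect_equal(brute_force_loglik(tr, y), manual, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on 200 random cases", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:6, 1)
    tr <- random_tree(n)
    y <- setNames(sample(0:1, n, TRUE), tr$tip.label)
    sp <- random_model_spec()
    if (sp$ascertainment == "no_absence_sites" && all(y == 0)) y[1] <- 1L
    if (runif(1) < 0.1) y[sample(n, 1)] <- NA   # missing data path
    expect_equal(character_loglik(tr, y, sp), brute_force_loglik(tr, y, sp),
                 tolerance = 1e-10)
  }
})

test_that("ascertainment-corrected pattern probabilities sum to one", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.6);")
  for (sp in list(model_spec(ascertainment = "no_absence_sites"),
                  model_spec("beta", gamma = TRUE,
                             ascertainment = "no_absence_sites",
                             gamma_shape = 0.7, beta_alpha = 2))) {
    pats <- as.matrix(expand.grid(rep(list(0:1), 4)))[-1, ]  # drop all-0
    tot <- sum(apply(pats, 1, function(p)
      exp(character_loglik(tr, setNames(p, c("A", "B", "C", "D")), sp))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("symmetric model is invariant under global 0/1 relabeling", {
  set.seed(5)
  tr <- random_tree(5)
  y <- setNames(c(0L, 1L, 1L, 0L, 1L), tr$tip.label)
  expect_equal(character_loglik(tr, y), character_loglik(tr, 1L - y),
               tolerance = 1e-12)
  ## all-present beats all-absent only when pi1 > 0.5
  sp_hi <- model_spec("beta", beta_alpha = 1, n_beta_cat = 1)
  ones <- setNames(rep(1L, 5), tr$tip.label)
  expect_equal(character_loglik(tr, ones, sp_hi),
               character_loglik(tr, 1L - ones, sp_hi), tolerance = 1e-12)
})

test_that("Beta mixture converges to the symmetric model as alpha grows", {
  set.seed(8)
  tr <- random_tree(5)
  y <- setNames(sample(0:1, 5, TRUE), tr$tip.label)
  sp_beta <- model_spec("beta", beta_alpha = 1e6)
  expect_equal(character_loglik(tr, y, sp_beta),
               character_loglik(tr, y, model_spec()), tolerance = 1e-6)
})

test_that("discrete gamma categories match phangorn's discretisation", {
  skip_if_not_installed("phangorn")
  for (shape in c(0.3, 1, 2.7)) {
    expect_equal(gamma_category_rates(shape, 4),
                 phangorn::discrete.gamma(shape, 4), tolerance = 1e-9)
  }
  expect_equal(mean(gamma_category_rates(0.6, 4)), 1, tolerance = 1e-12)
  expect_equal(mean(beta_category_freqs(0.7, 5)), 0.5, tolerance = 1e-12)
})

test_that("matrix_loglik reduces to its special cases", {
  set.seed(21)
  tr <- tree_7fix()
  m <- make_textile_like_dataset(n_chars = c(nonpile = 10, pile = 6))
  sp <- model_spec(ascertainment = "no_absence_sites")

  ## single character equals character_loglik
  m1 <- subset_characters(m, 1)
  expect_equal(matrix_loglik(tr, m1, sp),
               character_loglik(tr, setNames(m1$states[, 1],
                                             rownames(m1$states)), sp))

  ## unlinked rates with all multipliers 1 equal the linked model
  spu <- sp; spu$partition_rates <- "unlinked"
  expect_equal(
    matrix_loglik(tr, m, spu,
                  params = list(rate_multipliers = c(nonpile = 1, pile = 1))),
    matrix_loglik(tr, m, sp))

  ## unlinked topologies with identical trees equal the linked model
  spt <- sp; spt$topology <- "unlinked"
  expect_equal(matrix_loglik(list(nonpile = tr, pile = tr), m, spt),
               matrix_loglik(tr, m, sp))

  ## per-character decomposition sums to the total
  pc <- matrix_loglik(tr, m, sp, per_character = TRUE)
  expect_equal(sum(pc$per_character), pc$total)

  expect_error(matrix_loglik(list(nonpile = tr), m, spt), "pile")
})

test_that("posterior site rates behave as conditional gamma means", {
  set.seed(31)
  tr <- grafen_transform(parse_newick("((A,B),(C,(D,E)));"))
  taxa <- tr$tip.label
  s <- rbind(invar = rep(1L, 5),
             var1 = c(0L, 1L, 0L, 1L, 0L),
             var2 = c(1L, 0L, 1L, 0L, 1L))
  s <- t(s); rownames(s) <- taxa
  m <- character_matrix(s)
  spg <- model_spec(gamma = TRUE, gamma_shape = 0.8)
  ## a fabricated single-sample posterior at fixed parameters
  post <- structure(list(
    samples = data.frame(run = 1, generation = 1, lnL = 0,
                         gamma_shape = 0.8),
    trees = list(tree = list(tr))), class = "posterior_sample")
  r <- posterior_site_rates(post, m, spg)
  expect_lt(r[["invar"]], r[["var1"]])
  expect_lt(r[["invar"]], r[["var2"]])
  expect_true(all(r > 0))

  ## gamma off: rates exactly 1 by contract
  expect_equal(unname(posterior_site_rates(post, m, model_spec())),
               rep(1, 3))

  ## one rate category: every rate 1
  sp1 <- model_spec(gamma = TRUE, n_gamma_cat = 1)
  expect_equal(unname(posterior_site_rates(post, m, sp1)), rep(1, 3))
})

test_that("mean posterior rate is near 1 for homogeneous simulated data", {
  set.seed(77)
  tr <- tree_7fix()
  m <- simulate_characters(tr, 0.123, 300)
  ## evaluate on the tree in substitution units so the data are
  ## homogeneous *under the model* (relative rate 1)
  tr$edge.length <- tr$edge.length * 0.123
  post <- structure(list(
    samples = data.frame(run = 1, generation = 1, lnL = 0, gamma_shape = 2),
    trees = list(tree = list(tr))), class = "posterior_sample")
  r <- posterior_site_rates(post, m, model_spec(gamma = TRUE))
  expect_equal(mean(r), 1, tolerance = 0.05)
})
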