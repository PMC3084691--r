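test_that("character simulation: limits, reproducibility, closed form", {
  tr <- tree_7fix()
  ## near-zero rate: every taxon shares the root state
  set.seed(1)
  m <- simulate_characters(tr, 1e-9, 50)
  expect_true(all(apply(m$states, 2, function(y) length(unique(y)) == 1)))

  ## same seed, same matrix
  set.seed(7); a <- simulate_characters(tr, 0.123, 40)
  set.seed(7); b <- simulate_characters(tr, 0.123, 40)
  expect_identical(a$states, b$states)

  ## two-taxon mismatch fraction matches the closed form P01+P10 weighting
  t2 <- ape::read.tree(text = "(A:1.3,B:0.7);")
  set.seed(2)
  mm <- simulate_characters(t2, 0.4, 10000)
  p_mismatch <- 0.5 * (1 - exp(-2 * 0.4 * 2))   # total path length 2
  obs <- mean(mm$states["A", ] != mm$states["B", ])
  se <- sqrt(p_mismatch * (1 - p_mismatch) / 10000)
  expect_lt(abs(obs - p_mismatch), 3 * se)
})

test_that("transfer overlay semantics: no-op, swap, and adoption rate", {
  tr <- tree_7fix()
  set.seed(3)
  m <- simulate_characters(tr, 0.123, 30)
  m$outgroup <- "Pazyryk"

  ## adopt_prob = 0 leaves the matrix unchanged
  m0 <- suppressWarnings(apply_transfers(m, tr, transfer_config("local", 0)))
  expect_identical(m0$states, m$states)

  ## adopt_prob = 1 in a cherry: simultaneous update swaps the states
  states <- m$states
  states["Shahsevan", ] <- 0L; states["Yomut", ] <- 1L
  mc <- character_matrix(states, partition = m$partition,
                         outgroup = "Pazyryk")
  m1 <- suppressWarnings(apply_transfers(mc, tr, transfer_config("local", 1)))
  expect_true(all(m1$states["Shahsevan", ] == 1L))
  expect_true(all(m1$states["Yomut", ] == 0L))
  ## the outgroup and non-cherry taxa are untouched by local transfers
  expect_identical(m1$states["Pazyryk", ], mc$states["Pazyryk", ])
  expect_identical(m1$states["Qashqai", ], mc$states["Qashqai", ])

  ## realized adoption frequency ~ 30%: force donor different from host
  set.seed(4)
  states2 <- m$states
  states2["Bakhtiari", ] <- 0L; states2["Papi", ] <- 1L
  m2 <- character_matrix(states2, partition = m$partition,
                         outgroup = "Pazyryk")
  nrep <- 200
  changed <- replicate(nrep, {
    out <- suppressWarnings(apply_transfers(m2, tr,
                                            transfer_config("local", 0.3)))
    mean(out$states["Bakhtiari", ] != m2$states["Bakhtiari", ])
  })
  se <- sqrt(0.3 * 0.7 / (30 * nrep))
  expect_lt(abs(mean(changed) - 0.3), 3 * se)

  ## donor sets honour the tree neighbourhoods
  ds <- transfer_donor_sets(tr, "antilocal", textile_tribes())
  expect_setequal(ds$BoyerAhmad, c("Qashqai", "Bakhtiari", "Papi"))
  expect_length(ds$Shahsevan, 0)
})

test_that("invariant filtering removes exactly the constant characters", {
  s <- cbind(a = c(1L, 1L, 1L), b = c(0L, 1L, 0L), c = c(0L, 0L, 0L),
             d = c(1L, 0L, 1L))
  rownames(s) <- c("A", "B", "C")
  m <- character_matrix(s)
  md <- drop_invariant(m)
  expect_equal(colnames(md$states), c("b", "d"))

  expect_identical(drop_invariant(md)$states, md$states)
  expect_error(drop_invariant(character_matrix(s[, "a", drop = FALSE])),
               "invariant")
})

test_that("the textile-like generator reproduces the study layout", {
  set.seed(5)
  m <- make_textile_like_dataset()
  expect_equal(dim(m), c(7L, 122L))
  expect_equal(summarize_partitions(m)$size, c(42L, 56L, 24L))
  expect_equal(m$outgroup, "Pazyryk")

  ## two-partition incongruent layout carries both generating histories
  m2 <- make_textile_like_dataset(
    trees = list(pile = textile_reference_tree("pile")),
    n_chars = c(nonpile = 98, pile = 24))
  expect_equal(summarize_partitions(m2)$size, c(98L, 24L))
})

test_that("ML rate recovery: median near truth on a long tree", {
  set.seed(6)
  tr <- tree_7fix()
  tr$edge.length <- tr$edge.length * 2    # total length 48
  m <- simulate_characters(tr, 0.123, 5000)
  fit <- ml_rate(tr, m)
  expect_lt(abs(median(fit$rate) - 0.123) / 0.123, 0.15)
})

test_that("transfers increase homoplasy (parsimony steps) on average", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  tr <- tree_7fix()
  steps <- function(m) {
    pd <- phangorn::phyDat(m$states, type = "USER", levels = c(0, 1))
    sum(phangorn::parsimony(tr, pd))
  }
  diffs <- replicate(40, {
    m <- simulate_characters(tr, 0.123, 30)
    m$outgroup <- "Pazyryk"
    mt <- suppressWarnings(apply_transfers(m, tr,
                                           transfer_config("global", 0.3)))
    steps(mt) - steps(m)
  })
  expect_gt(mean(diffs), 0)
})
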