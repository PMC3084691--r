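test_that("ml_rate flags invariant characters at the lower bound", {
  tr <- tree_7fix()
  y <- setNames(rep(1L, 7), tr$tip.label)
  fit <- ml_rate(tr, y)
  expect_equal(fit$rate, 1e-8)
  expect_equal(fit$bound_hit, "lower")
})

test_that("ml_rate agrees with a dense log-grid search", {
  set.seed(12)
  tr <- tree_7fix()
  m <- simulate_characters(tr, 0.123, 12)
  m <- drop_invariant(m)
  fit <- ml_rate(tr, m)
  taxa <- rownames(m$states)
  grid <- exp(seq(log(1e-8), log(100), length.out = 2000))
  for (j in seq_len(ncol(m$states))) {
    y <- setNames(m$states[, j], taxa)
    ll <- vapply(grid, function(r)
      character_loglik(tr, y, params = list(rate = r)), numeric(1))
    ghat <- grid[which.max(ll)]
    ## saturating characters have a flat likelihood plateau in the rate;
    ## there the achieved maximum must match, elsewhere the argmax too
    expect_lt(abs(fit$lnL[j] - max(ll)), 1e-4)
    if (ghat < 1) expect_lt(abs(fit$rate[j] - ghat) / ghat, 0.01)
  }
})

test_that("ml_rate agrees with an independent Mk fitter", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tr <- tree_7fix()
  m <- drop_invariant(simulate_characters(tr, 0.3, 8))
  fit <- ml_rate(tr, m)
  for (j in seq_len(min(6, ncol(m$states)))) {
    if (fit$rate[j] >= 1) next   # saturation plateau: rate unidentifiable
    x <- setNames(as.character(m$states[, j]), rownames(m$states))
    ref <- phytools::fitMk(tr, x, model = "ER",
                           pi = c(0.5, 0.5))
    q <- ref$rates[1]
    if (q > 1.01e-8 && q < 99) {
      expect_lt(abs(fit$rate[j] - q) / q, 0.05)
    }
  }
})

test_that("ml_rate is scale-consistent in branch lengths", {
  set.seed(14)
  tr <- random_tree(6, bl_mean = 1)
  m <- drop_invariant(simulate_characters(tr, 0.5, 6))
  f1 <- ml_rate(tr, m)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  f2 <- ml_rate(tr2, m)
  keep <- f1$bound_hit == "none" & f2$bound_hit == "none" & f1$rate < 1
  expect_true(any(keep))
  expect_equal(f2$rate[keep], f1$rate[keep] / 3, tolerance = 0.01)
})

test_that("Mann-Whitney U: exact enumeration, symmetry, tie handling", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)            # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")

  x <- c(1, 2, 3, 4)
  ri <- mann_whitney_u(x, x)
  expect_equal(ri$U, length(x)^2 / 2)
  expect_gte(ri$p, 0.99)

  ## agreement with stats::wilcox.test (the independent route)
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(sample(4:8, 1)); b <- rnorm(sample(4:8, 1), mean = 0.5)
    mine <- mann_whitney_u(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE,
                                        correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_lt(abs(mine$p - ref$p.value), 0.02)
  }

  ## exact and approximate modes agree for 6+6 samples
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- mann_whitney_u(a, b, exact_max = 12)$p
    pa <- mann_whitney_u(a, b, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("variance tests: scaling, F dfs, Fligner-Killeen hand check", {
  set.seed(16)
  x <- rnorm(98); y <- rnorm(24)
  v <- variance_tests(x, y)
  expect_equal(v$F_ratio, var(x) / var(y), tolerance = 1e-12)
  expect_equal(v$df, c(97, 23), ignore_attr = TRUE)

  v2 <- variance_tests(2 * y, y)
  expect_equal(v2$F_ratio, 4, tolerance = 1e-12)

  ## Fligner-Killeen by the published formula on a 6+6 example
  a <- c(51, 87, 50, 48, 79, 61); b <- c(82, 91, 92, 80, 52, 79)
  centred <- c(abs(a - median(a)), abs(b - median(b)))
  sc <- qnorm(0.5 + rank(centred) / (2 * (length(centred) + 1)))
  g <- rep(1:2, each = 6)
  abar <- tapply(sc, g, mean)
  stat_hand <- sum(6 * (abar - mean(sc))^2) / var(sc)
  vh <- variance_tests(a, b)
  expect_equal(vh$fk_stat, unname(stat_hand), tolerance = 1e-9)
  expect_equal(vh$fk_p, pchisq(stat_hand, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  expect_error(variance_tests(x, rep(1, 5)), "zero variance")
})

test_that("summarize_rates bundles the comparisons coherently", {
  set.seed(17)
  rates <- c(rexp(98, 5), rexp(24, 5))
  grp <- rep(c("nonpile", "pile"), c(98, 24))
  rep1 <- summarize_rates(rates, grp)
  expect_equal(unname(rep1$n), c(98L, 24L))
  expect_true(rep1$U_p >= 0 && rep1$U_p <= 1)

  ## identical groups: no median difference, calm p values
  r2 <- summarize_rates(rep(c(1, 2, 3, 4), 2), rep(c("a", "b"), each = 4))
  expect_equal(unname(diff(r2$median)), 0)
  expect_gt(r2$U_p, 0.9)

  ## shifted distributions are detected with large samples
  r3 <- summarize_rates(c(rnorm(80), rnorm(80, 2)),
                        rep(c("a", "b"), each = 80))
  expect_lt(r3$U_p, 1e-4)

  ## report round-trips through CSV
  df <- as.data.frame(r2)
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  expect_equal(read.csv(p)$median, df$median)
  unlink(p)
})
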