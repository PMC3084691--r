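test_that("newick parsing and writing round-trip", {
  for (txt in c("((A:1,B:1):2,C:3);",
                "(Pazyryk,((Shahsevan,Yomut),(Qashqai,(BoyerAhmad,(Bakhtiari,Papi)))));")) {
    tr <- parse_newick(txt)
    tr2 <- parse_newick(write_newick(tr))
    expect_setequal(tr$tip.label, tr2$tip.label)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  }
  expect_error(parse_newick("((A,B),C;"), "parenthes")
  expect_error(parse_newick("(A,B));"), "parenthes")
})

test_that("Grafen transformation sets node ages to descendants minus one", {
  ## 7-taxon reference: root age 6
  tr <- textile_reference_tree(grafen = FALSE)
  g <- grafen_transform(tr)
  ages <- node_ages(g)
  expect_equal(unname(ages[ape::Ntip(g) + 1]), 6)
  expect_true(all(abs(ages[seq_len(ape::Ntip(g))]) < 1e-12))

  ## any cherry: age 1, two pendant branches of length 1
  ch <- grafen_transform(parse_newick("(A,B);"))
  expect_equal(sort(ch$edge.length), c(1, 1))

  ## balanced 4-taxon: root age 3, cherries at 1, cherry->root length 2
  b4 <- grafen_transform(parse_newick("((A,B),(C,D));"))
  a4 <- node_ages(b4)
  expect_equal(sort(unname(a4[a4 > 0])), c(1, 1, 3))
  expect_equal(sort(b4$edge.length), c(1, 1, 1, 1, 2, 2))

  expect_error(grafen_transform(ape::unroot(parse_newick("((A,B),(C,D),E);"))),
               "root")
})

test_that("Grafen output is ultrametric for random topologies", {
  set.seed(3)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:10, 1), rooted = TRUE)
    g <- grafen_transform(tr)
    d <- ape::node.depth.edgelength(g)[seq_len(ape::Ntip(g))]
    expect_lt(diff(range(d)), 1e-10)
    ## cross-check against ape's normalised Grafen heights scaled back up
    ga <- ape::compute.brlen(tr, method = "Grafen", power = 1)
    expect_equal(g$edge.length,
                 ga$edge.length * (ape::Ntip(tr) - 1), tolerance = 1e-9)
  }
})

test_that("taxon neighborhoods count internal-node separation", {
  ch <- parse_newick("((A:1,B:1):1,(C:1,D:1):2);")
  expect_equal(taxon_neighborhood(ch, "A", 1), "B")
  expect_setequal(taxon_neighborhood(ch, "A", 2), c("C", "D"))
  expect_error(taxon_neighborhood(ch, "Z", 1), "unknown taxon")

  fix <- textile_reference_tree()
  expect_equal(taxon_neighborhood(fix, "Papi", 1), "Bakhtiari")
  expect_equal(taxon_neighborhood(fix, "Shahsevan", 1), "Yomut")
  ## ladder section: Qashqai's sisters are one clade away
  expect_setequal(taxon_neighborhood(fix, "Qashqai", 2),
                  c("Pazyryk", "BoyerAhmad"))
  expect_setequal(taxon_neighborhood(fix, "BoyerAhmad", 2),
                  c("Qashqai", "Bakhtiari", "Papi"))
})

test_that("clade constraints are monophyly checks", {
  tr <- parse_newick("((A,B),C);")
  expect_true(check_constraint(tr, c("A", "B")))
  expect_false(check_constraint(parse_newick("((A,C),B);"), c("A", "B")))
  expect_true(check_constraint(tr, c("A", "B", "C")))
  expect_true(check_constraint(tr, "A"))
  expect_error(check_constraint(tr, c("A", "Z")), "unknown")
})
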