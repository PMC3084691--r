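# shared fixtures and independent oracles for the test suite

# canonical key of a rooted topology: sorted clade strings
topo_key <- function(tr) {
  pp <- unclass(ape::prop.part(tr))
  paste(sort(vapply(pp, function(p)
    paste(sort(tr$tip.label[p]), collapse = "+"), character(1))),
    collapse = "|")
}

# all 15 rooted binary labeled topologies on 4 taxa
rooted_topologies4 <- function(taxa = c("A", "B", "C", "D")) {
  out <- character(0)
  for (p in list(c(1, 2), c(1, 3), c(1, 4))) {
    q <- setdiff(1:4, p)
    out <- c(out, sprintf("((%s,%s),(%s,%s));", taxa[p[1]], taxa[p[2]],
                          taxa[q[1]], taxa[q[2]]))
  }
  for (i in 1:4) for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    r <- setdiff(1:4, i)
    cher <- r[p]; mid <- setdiff(r, cher)
    out <- c(out, sprintf("(%s,(%s,(%s,%s)));", taxa[i], taxa[mid],
                          taxa[cher[1]], taxa[cher[2]]))
  }
  out
}

# exact marginal likelihood of a small 0/1 matrix on a rooted topology,
# with iid Exp(mean mu) branch-length priors integrated analytically:
# sum over joint internal-state assignments; each edge contributes
# E[prod_c P_c(t)] = 0.5^C * sum_k coef_k * lambda / (lambda + 2k).
exact_marginal4 <- function(topo_txt, X, mu = 0.1) {
  tr <- ape::read.tree(text = topo_txt)
  n <- ape::Ntip(tr)
  C <- ncol(X)
  lam <- 1 / mu
  Ek <- lam / (lam + 2 * (0:C))
  tr2 <- reorder(tr, "postorder")
  perm <- match(tr2$tip.label, rownames(X))
  nint <- tr$Nnode
  total <- 0
  for (a in seq_len(2^(nint * C)) - 1L) {
    bits <- as.integer(intToBits(a))[seq_len(nint * C)]
    s <- rbind(X[perm, , drop = FALSE], matrix(bits, nint, C))
    pr <- 0.5^C
    for (k in seq_len(nrow(tr2$edge))) {
      sgn <- ifelse(s[tr2$edge[k, 1], ] == s[tr2$edge[k, 2], ], 1, -1)
      co <- 1
      for (g in sgn) co <- c(co, 0) + c(0, co * g)
      pr <- pr * 0.5^C * sum(co * Ek[seq_along(co)])
    }
    total <- total + pr
  }
  total
}

# small reusable trees
tree_cherry4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);")
tree_7fix <- function() textile_reference_tree("all")

# random rooted tree with taxa t1..tn and exp branch lengths
random_tree <- function(n, bl_mean = 0.3) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- rexp(nrow(tr$edge), 1 / bl_mean)
  tr
}

random_model_spec <- function() {
  model_spec(asymmetry = sample(c("symmetric", "beta"), 1),
             gamma = sample(c(TRUE, FALSE), 1),
             ascertainment = sample(c("none", "no_absence_sites"), 1),
             gamma_shape = runif(1, 0.3, 3),
             beta_alpha = runif(1, 0.3, 3))
}
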