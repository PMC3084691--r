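#' Parse and write newick trees
#'
#' Thin, validating wrappers around `ape`'s newick reader/writer.  Trees
#' are handled rooted throughout the package; the root may have degree two
#' (the usual outgroup attachment).
#'
#' @param text a newick string.
#' @return `parse_newick()` returns an `ape::phylo`; `write_newick()` a
#'   newick string terminated with `;`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1)
    stop("expected a single newick string")
  depth <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
  if (any(depth < 0) || tail(depth, 1) != 0)
    stop("unbalanced parentheses in newick string at position ",
         if (any(depth < 0)) which(depth < 0)[1] else nchar(text))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable string")
  tr
}

#' @rdname parse_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Grafen transformation to an ultrametric tree
#'
#' Ignores any branch lengths on the input and sets the age of each
#' internal node to one less than its number of descendant tips, with all
#' tips at age zero; each branch length becomes the difference between the
#' ages of its two ends.  This is the standard way to equip a bare
#' topology with branch lengths roughly proportional to time when no
#' temporal information is available: a tree of N tips gets root age
#' N - 1.  Note the ages are used as-is (no rescaling of the root to 1).
#'
#' @param tree a rooted `ape::phylo` (polytomies allowed).
#' @return An ultrametric `ape::phylo` with the same topology.
#' @export
grafen_transform <- function(tree) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; root it (e.g. on the outgroup) first")
  n <- ape::Ntip(tree)
  tr2 <- stats::reorder(tree, "postorder")
  ndesc <- integer(n + tree$Nnode)
  ndesc[seq_len(n)] <- 1L
  for (k in seq_len(nrow(tr2$edge)))
    ndesc[tr2$edge[k, 1]] <- ndesc[tr2$edge[k, 1]] + ndesc[tr2$edge[k, 2]]
  age <- ifelse(seq_along(ndesc) <= n, 0, ndesc - 1L)
  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  out
}

#' Node ages of an ultrametric tree
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return Numeric vector of ages (root-to-node depth subtracted from tree
#'   height), indexed like the tree's internal node numbering.
#' @export
node_ages <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

is_ultrametric <- function(tree, tol = 1e-8) {
  n <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(n)]
  diff(range(d)) < tol
}

#' Tips separated from a taxon by exactly k internal nodes
#'
#' Counts the internal nodes crossed on the path between two tips on the
#' unrooted form of the tree (a degree-two root is suppressed, as it is
#' not a node of the unrooted topology).  `k = 1` gives the sister taxa
#' (cherry mates, or co-members of a polytomy); `k = 2` the "anti-local"
#' donors of the borrowing simulations.
#'
#' @param tree a rooted `ape::phylo`.
#' @param taxon a tip label.
#' @param k internal-node separation (1 or 2 in the study design; any
#'   positive integer accepted).
#' @return Character vector of tip labels at separation exactly `k`
#'   (possibly empty).
#' @export
taxon_neighborhood <- function(tree, taxon, k) {
  i <- match(taxon, tree$tip.label)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  stopifnot(k >= 1)
  sep <- .tip_separation(tree)[i, ]
  tree$tip.label[sep == k & seq_along(sep) != i]
}

## matrix of pairwise internal-node counts between tips (unrooted sense)
.tip_separation <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  root_degree <- sum(tree$edge[, 1] == root)
  D <- matrix(0L, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pth <- ape::nodepath(tree, i, j)
    ints <- pth[pth > n]
    if (root_degree == 2L) ints <- setdiff(ints, root)
    D[i, j] <- D[j, i] <- length(ints)
  }
  D
}

#' Is a set of taxa monophyletic in a tree?
#'
#' Used to enforce and check topology constraints (for example "Papi
#' sister to Bakhtiari" is the constraint clade `c("Papi", "Bakhtiari")`).
#'
#' @param tree a rooted `ape::phylo`.
#' @param clade character vector of tip labels (a subset of the tree's
#'   taxa).
#' @return `TRUE` iff the clade is a monophyletic group of `tree`.
#' @export
check_constraint <- function(tree, clade) {
  if (!all(clade %in% tree$tip.label))
    stop("constraint clade contains unknown taxa: ",
         paste(setdiff(clade, tree$tip.label), collapse = ", "))
  if (length(clade) <= 1 || length(clade) == ape::Ntip(tree)) return(TRUE)
  ape::is.monophyletic(tree, clade)
}

#' Reference trees of the textile study design
#'
#' Fixed 7-taxon topologies used by the synthetic-data generator: six
#' ingroup tribes plus the archaeological outgroup assemblage (Pazyryk).
#' The `"all"` tree is the reconstruction of the source study's
#' all-character topology (Papi sister to Bakhtiari); the `"pile"` tree
#' moves Papi basal to the Qashqai/BoyerAhmad/Bakhtiari clade, the
#' topological shift reported for pile-weave design characters.  Both are
#' approximate reconstructions from the published figure descriptions, not
#' machine-read topologies.
#'
#' @param role `"all"` (default) or `"pile"`.
#' @param grafen logical; return the Grafen-transformed ultrametric form
#'   (default `TRUE`) rather than the bare topology.
#' @return An `ape::phylo`.
#' @export
textile_reference_tree <- function(role = c("all", "pile"), grafen = TRUE) {
  role <- match.arg(role)
  txt <- switch(role,
    all  = "(Pazyryk,((Shahsevan,Yomut),(Qashqai,(BoyerAhmad,(Bakhtiari,Papi)))));",
    pile = "(Pazyryk,((Shahsevan,Yomut),(Papi,(Qashqai,(BoyerAhmad,Bakhtiari)))));")
  tr <- parse_newick(txt)
  if (grafen) grafen_transform(tr) else tr
}

#' @rdname textile_reference_tree
#' @export
textile_tribes <- function() {
  c("Shahsevan", "Yomut", "Qashqai", "BoyerAhmad", "Bakhtiari", "Papi")
}

#' @rdname textile_reference_tree
#' @export
textile_outgroup <- function() "Pazyryk"
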