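#' Majority-rule consensus tree with clade credibilities
#'
#' Builds the consensus of a posterior sample of rooted trees from the
#' clades whose frequency exceeds `threshold` (such clades are mutually
#' compatible for any threshold >= 0.5).  Each retained node is annotated
#' with its clade credibility — the proportion of sample trees containing
#' that clade — and receives the mean length, over the trees containing
#' the clade, of the branch subtending it.
#'
#' @param trees a list of rooted `ape::phylo` objects (or an
#'   `ape::multiPhylo`) on one common taxon set.
#' @param threshold minimum clade frequency, default 0.5 (strict
#'   majority).  Values below 0.5 are rejected since clades could then be
#'   incompatible.
#' @return A list with elements `tree` (an `ape::phylo`; node labels carry
#'   the credibilities, branch lengths are means) and `clades` (a data
#'   frame with one row per clade seen in the sample: members, frequency,
#'   mean subtending branch length).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("empty tree sample")
  if (threshold < 0.5) stop("threshold below 0.5 can select incompatible clades")
  taxa <- sort(trees[[1]]$tip.label)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  blsums <- new.env(hash = TRUE, parent = emptyenv())
  tipbl <- setNames(numeric(length(taxa)), taxa)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa) ||
        length(tr$tip.label) != length(taxa))
      stop("trees are not all on the same taxon set")
    n <- ape::Ntip(tr)
    elen <- setNames(rep(NA_real_, n + tr$Nnode), NULL)
    elen[tr$edge[, 2]] <- tr$edge.length
    tipbl[tr$tip.label] <- tipbl[tr$tip.label] +
      elen[seq_len(n)] / length(trees)
    sets <- .clade_sets(tr)
    for (nd in seq_along(sets)) {
      if (is.null(sets[[nd]])) next
      key <- paste(sets[[nd]], collapse = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      bl <- elen[n + nd]
      if (!is.na(bl)) blsums[[key]] <- (blsums[[key]] %||% 0) + bl
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1)) / length(trees)
  meanbl <- vapply(keys, function(k) {
    (blsums[[k]] %||% NA_real_) / counts[[k]]
  }, numeric(1))
  clades <- data.frame(clade = gsub("\r", ",", keys), frequency = freq,
                       mean_brlen = meanbl, row.names = NULL,
                       stringsAsFactors = FALSE)
  clades <- clades[order(-clades$frequency, clades$clade), ]
  keep <- keys[freq > threshold | vapply(keys, function(k) {
    length(strsplit(k, "\r")[[1]]) == length(taxa)
  }, logical(1))]
  tree <- .build_from_clades(lapply(strsplit(keep, "\r"), identity),
                             freq[keep], meanbl[keep], taxa, tipbl)
  list(tree = tree, clades = clades)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-internal-node sorted tip-label sets (index = node - Ntip)
.clade_sets <- function(tr) {
  n <- ape::Ntip(tr)
  tr2 <- stats::reorder(tr, "postorder")
  sets <- vector("list", tr$Nnode)
  acc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) acc[[i]] <- tr$tip.label[i]
  for (k in seq_len(nrow(tr2$edge))) {
    p <- tr2$edge[k, 1]; ch <- tr2$edge[k, 2]
    acc[[p]] <- c(acc[[p]], acc[[ch]])
  }
  for (nd in seq_len(tr$Nnode))
    sets[[nd]] <- sort(acc[[n + nd]])
  sets
}

## assemble a rooted tree from nested (compatible) clades;
## node labels = frequencies, branch lengths = means
.build_from_clades <- function(sets, freq, meanbl, taxa, tipbl) {
  ## ensure the root clade (all taxa) is present
  sizes <- vapply(sets, length, integer(1))
  if (!any(sizes == length(taxa))) {
    sets <- c(sets, list(taxa)); freq <- c(freq, 1); meanbl <- c(meanbl, NA)
    sizes <- c(sizes, length(taxa))
  }
  o <- order(-sizes)
  sets <- sets[o]; freq <- freq[o]; meanbl <- meanbl[o]
  nclade <- length(sets)
  ## parent of clade i = smallest clade strictly containing it; because the
  ## clades are mutually compatible the first later-sorted strict superset
  ## scan works on the size-descending order reversed
  parent_of <- function(i) {
    cands <- which(vapply(seq_len(nclade), function(j) {
      j != i && length(sets[[j]]) > length(sets[[i]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
    cands[which.min(vapply(cands, function(j) length(sets[[j]]), integer(1)))]
  }
  tip_parent <- vapply(taxa, function(tx) {
    cands <- which(vapply(seq_len(nclade), function(j) tx %in% sets[[j]],
                          logical(1)))
    cands[which.min(vapply(cands, function(j) length(sets[[j]]), integer(1)))]
  }, integer(1))
  kids_clade <- lapply(seq_len(nclade), function(i) {
    which(vapply(seq_len(nclade), function(j)
      j != i && identical(parent_of(j), i), logical(1)))
  })
  emit <- function(i) {
    parts <- c(
      vapply(which(tip_parent == i), function(t)
        sprintf("%s:%.10g", taxa[t], tipbl[taxa[t]]), character(1)),
      vapply(kids_clade[[i]], function(j)
        sprintf("%s%.6g:%.10g", emit(j), freq[j],
                if (is.na(meanbl[j])) 0 else meanbl[j]), character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- sprintf("%s%.6g;", emit(1L), freq[1])
  ape::read.tree(text = nwk)
}
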