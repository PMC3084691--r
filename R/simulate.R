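#' Configuration of a tip-level horizontal-transfer overlay
#'
#' @param mode donor regime: `"local"` (donors are sister taxa, one
#'   internal node away), `"antilocal"` (donors exactly two internal
#'   nodes away; sisters never donate), or `"global"` (any other eligible
#'   taxon).
#' @param adopt_prob per-taxon, per-character adoption probability
#'   (default 0.30, the study value).
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(mode = c("local", "antilocal", "global"),
                            adopt_prob = 0.30) {
  stopifnot(adopt_prob >= 0, adopt_prob <= 1)
  structure(list(mode = match.arg(mode), adopt_prob = adopt_prob),
            class = "transfer_config")
}

#' Simulate binary characters along a tree
#'
#' Two-state symmetric chain: the root state is drawn from the stationary
#' frequencies (1/2, 1/2) and evolved edge by edge with flip probability
#' `0.5 * (1 - exp(-2 * rate * branch_length))`, i.e. the same
#' normalisation as [transition_prob()] at `pi1 = 0.5`, so `rate` is in
#' expected changes per unit branch length.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param rate instantaneous transition rate (> 0); study default 0.123.
#' @param n_chars number of characters.
#' @param partition_label label assigned to all simulated characters.
#' @param char_names optional character names.
#' @return A [character_matrix()].
#' @export
simulate_characters <- function(tree, rate = 0.123, n_chars,
                                partition_label = "all",
                                char_names = NULL) {
  stopifnot(rate > 0, n_chars >= 1)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  tr2 <- stats::reorder(tree, "postorder")
  states <- matrix(NA_integer_, n + tree$Nnode, n_chars)
  states[n + 1L, ] <- rbinom(n_chars, 1, 0.5)
  for (k in rev(seq_len(nrow(tr2$edge)))) {   # preorder traversal
    p <- tr2$edge[k, 1]; ch <- tr2$edge[k, 2]
    pflip <- 0.5 * (1 - exp(-2 * rate * tr2$edge.length[k]))
    flip <- rbinom(n_chars, 1, pflip) == 1L
    states[ch, ] <- ifelse(flip, 1L - states[p, ], states[p, ])
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- char_names %||% paste0(partition_label,
                                          seq_len(n_chars))
  character_matrix(out, partition = partition_label)
}

#' Overlay horizontal transfers on a simulated matrix
#'
#' For each character and each eligible taxon independently, with
#' probability `cfg$adopt_prob` the taxon replaces its state with the
#' state of a donor drawn uniformly from its mode-specific donor set.
#' All adoptions read the *pre-transfer* states (simultaneous update), so
#' a mutual adoption within a cherry swaps the two states.  Taxa whose
#' donor set is empty under the chosen mode (for example non-cherry taxa
#' in local mode) are skipped with a one-time warning.
#'
#' @param m a [character_matrix()].
#' @param tree the tree defining the donor neighbourhoods (see
#'   [taxon_neighborhood()]).
#' @param cfg a [transfer_config()].
#' @param eligible taxa that may donate and receive; defaults to all taxa
#'   except the matrix's outgroup (an archaeological assemblage neither
#'   borrows nor donates).
#' @return A [character_matrix()] with transferred states.
#' @export
apply_transfers <- function(m, tree, cfg,
                            eligible = setdiff(rownames(m$states),
                                               m$outgroup)) {
  stopifnot(inherits(cfg, "transfer_config"))
  s <- m$states
  if (!all(eligible %in% rownames(s)))
    stop("eligible taxa not in matrix: ",
         paste(setdiff(eligible, rownames(s)), collapse = ", "))
  donors <- transfer_donor_sets(tree, cfg$mode, eligible)
  empty <- names(donors)[lengths(donors) == 0]
  if (length(empty))
    warning("no ", cfg$mode, " donors for: ",
            paste(empty, collapse = ", "), " (skipped)")
  if (cfg$adopt_prob == 0) return(m)
  out <- s
  for (tx in eligible) {
    ds <- donors[[tx]]
    if (!length(ds)) next
    adopt <- which(runif(ncol(s)) < cfg$adopt_prob)
    if (!length(adopt)) next
    d <- match(sample(ds, length(adopt), replace = TRUE), rownames(s))
    out[tx, adopt] <- s[cbind(d, adopt)]
  }
  character_matrix(out, partition = m$partition, outgroup = m$outgroup,
                   validate = FALSE)
}

#' @rdname apply_transfers
#' @param mode a transfer mode (see [transfer_config()]).
#' @export
transfer_donor_sets <- function(tree, mode, eligible) {
  setNames(lapply(eligible, function(tx) {
    if (mode == "global") return(setdiff(eligible, tx))
    k <- if (mode == "local") 1L else 2L
    intersect(taxon_neighborhood(tree, tx, k), setdiff(eligible, tx))
  }), eligible)
}

#' Remove invariant characters
#'
#' Drops every character whose observed state is identical across all
#' taxa (missing entries ignored), preserving the order of the
#' survivors.
#'
#' @param m a [character_matrix()].
#' @return A [character_matrix()] of the variable characters.
#' @export
drop_invariant <- function(m) {
  keep <- apply(m$states, 2, function(y) {
    u <- unique(y[!is.na(y)]); length(u) > 1
  })
  if (!any(keep)) stop("all characters are invariant")
  subset_characters(m, which(keep))
}

#' Synthetic dataset emulating the textile study design
#'
#' Simulates the study's 7-taxon, 122-character layout: 42 "techniques"
#' and 56 "flat" (flat-weave design) characters plus 24 "pile" (pile-weave
#' design) characters, each partition evolved as a two-state chain on its
#' assigned tree.  With one tree the partitions share a single history
#' (the congruent null); giving the pile partition a different tree (for
#' example [textile_reference_tree]`("pile")`) produces the incongruent
#' two-history scenario.  Optional per-partition transfer overlays and
#' invariant filtering complete the generator.
#'
#' @param tree tree for all partitions not listed in `trees`.
#' @param trees optional named list of per-partition trees overriding
#'   `tree`.
#' @param n_chars named integer vector of partition sizes; default
#'   `c(techniques = 42, flat = 56, pile = 24)`.
#' @param rate transition rate (single value or named per partition).
#' @param transfer optional named list of [transfer_config()]s per
#'   partition.
#' @param filter_invariant logical; remove invariant characters at the
#'   end (see [drop_invariant()]).
#' @param outgroup outgroup label recorded in the matrix.
#' @return A [character_matrix()].
#' @export
make_textile_like_dataset <- function(tree = textile_reference_tree(),
                                      trees = list(),
                                      n_chars = c(techniques = 42,
                                                  flat = 56, pile = 24),
                                      rate = 0.123,
                                      transfer = list(),
                                      filter_invariant = FALSE,
                                      outgroup = textile_outgroup()) {
  stopifnot(length(n_chars) >= 1, all(n_chars >= 1))
  if (is.null(names(n_chars)))
    names(n_chars) <- paste0("p", seq_along(n_chars))
  rates <- if (length(rate) == 1)
    setNames(rep(rate, length(n_chars)), names(n_chars)) else rate
  parts <- lapply(names(n_chars), function(l) {
    tr <- trees[[l]] %||% tree
    mm <- simulate_characters(tr, rates[[l]], n_chars[[l]],
                              partition_label = l)
    mm$outgroup <- if (!is.null(outgroup) &&
                       outgroup %in% rownames(mm$states)) outgroup else NULL
    if (!is.null(transfer[[l]]))
      mm <- apply_transfers(mm, tr, transfer[[l]])
    mm
  })
  taxa <- rownames(parts[[1]]$states)
  states <- do.call(cbind, lapply(parts, function(p) p$states[taxa, ,
                                                              drop = FALSE]))
  partition <- unlist(lapply(parts, function(p) unname(p$partition)))
  names(partition) <- colnames(states)
  out <- character_matrix(states, partition = partition,
                          outgroup = if (!is.null(outgroup) &&
                                         outgroup %in% taxa) outgroup
                                     else NULL)
  if (filter_invariant) drop_invariant(out) else out
}
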