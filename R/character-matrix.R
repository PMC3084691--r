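#' Construct a binary character matrix with partition labels
#'
#' The basic data container of the package: an N_taxa x N_chars matrix of
#' presence/absence states (0, 1, or `NA` for missing, coded `?` on disk),
#' a partition label for every character, and an optional outgroup taxon.
#'
#' @param states integer/numeric matrix of 0/1/`NA` with taxa as rows and
#'   characters as columns.  Row names are taxon names; column names are
#'   character names (generated as `c1`, `c2`, ... when absent).
#' @param partition character vector of partition labels, either length 1
#'   (recycled) or one per character; or a named vector mapping character
#'   name to label.
#' @param outgroup optional taxon name used for rooting.
#' @param validate logical; check the container invariants (default `TRUE`).
#' @param strict logical; additionally require that no character is absent
#'   (0 or missing) in every taxon, the convention for observational
#'   presence/absence data where a character enters the matrix only if it
#'   was seen somewhere.
#'
#' @return An object of class `character_matrix`: a list with elements
#'   `states`, `partition` (named character vector) and `outgroup`.
#' @seealso [read_matrix()], [summarize_partitions()], [drop_invariant()]
#' @export
character_matrix <- function(states, partition = "all", outgroup = NULL,
                             validate = TRUE, strict = FALSE) {
  states <- as.matrix(states)
  if (is.null(rownames(states)))
    stop("taxon names required as row names of `states`")
  if (is.null(colnames(states)) && ncol(states) > 0)
    colnames(states) <- paste0("c", seq_len(ncol(states)))
  storage.mode(states) <- "integer"
  if (!is.null(names(partition)) && length(partition) > 1) {
    partition <- partition[colnames(states)]
  } else if (length(partition) == 1) {
    partition <- rep(partition, ncol(states))
  }
  partition <- as.character(partition)
  names(partition) <- colnames(states)
  m <- structure(list(states = states, partition = partition,
                      outgroup = outgroup),
                 class = "character_matrix")
  if (validate) validate_matrix(m, strict = strict)
  m
}

#' Validate a character matrix
#'
#' Checks the container invariants and fails with the offending taxon or
#' character name in the message.
#'
#' @param m a [character_matrix()].
#' @param strict logical; also reject characters absent (0/missing) in all
#'   taxa.
#' @return `m`, invisibly, if valid.
#' @export
validate_matrix <- function(m, strict = FALSE) {
  stopifnot(inherits(m, "character_matrix"))
  s <- m$states
  tn <- rownames(s); cn <- colnames(s)
  if (anyDuplicated(tn))
    stop("duplicate taxon name: ", tn[duplicated(tn)][1])
  if (anyDuplicated(cn))
    stop("duplicate character name: ", cn[duplicated(cn)][1])
  bad <- !(s %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    j <- arrayInd(which(bad)[1], dim(s))
    stop("non-binary state ", s[bad][1], " for taxon ", tn[j[1]],
         ", character ", cn[j[2]])
  }
  if (length(m$partition) != ncol(s) ||
      !identical(names(m$partition), cn) || anyNA(m$partition))
    stop("every character needs exactly one partition label")
  if (!is.null(m$outgroup) && !(m$outgroup %in% tn))
    stop("outgroup ", m$outgroup, " is not among the taxa")
  if (strict && ncol(s) > 0) {
    present <- colSums(s == 1L, na.rm = TRUE)
    if (any(present == 0))
      stop("character absent in all taxa: ", cn[present == 0][1])
  }
  invisible(m)
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d binary characters\n",
              nrow(x$states), ncol(x$states)))
  ps <- summarize_partitions(x)
  cat("partitions:", paste(sprintf("%s=%d", ps$label, ps$size),
                           collapse = ", "), "\n")
  if (!is.null(x$outgroup)) cat("outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$states)

#' Count characters per partition
#'
#' @param m a [character_matrix()].
#' @return A data frame with columns `label` and `size`, one row per
#'   partition in order of first appearance in the matrix.
#' @export
summarize_partitions <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  labs <- unique(m$partition)
  data.frame(label = labs,
             size = as.integer(table(factor(m$partition, levels = labs))),
             stringsAsFactors = FALSE)
}

#' Subset the characters of a matrix
#'
#' @param m a [character_matrix()].
#' @param chars character names or column indices to keep (order preserved).
#' @return A [character_matrix()] restricted to those characters.
#' @export
subset_characters <- function(m, chars) {
  s <- m$states[, chars, drop = FALSE]
  character_matrix(s, partition = m$partition[colnames(s)],
                   outgroup = m$outgroup, validate = FALSE)
}

## split into one character_matrix per partition (order of first appearance)
split_partitions <- function(m) {
  labs <- unique(m$partition)
  setNames(lapply(labs, function(l) {
    subset_characters(m, names(m$partition)[m$partition == l])
  }), labs)
}
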