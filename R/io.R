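#' Read a character matrix from NEXUS or CSV
#'
#' NEXUS files use a `DATA` block with `datatype=standard`, symbols `01`
#' and missing symbol `?`; partitions are read from `charset` statements in
#' a `SETS` (or `ASSUMPTIONS`) block.  CSV files hold taxa as rows and
#' characters as columns, first column taxon names, first row character
#' names; the partition map is a companion two-column CSV
#' (`character,partition`) whose default location is
#' `<path>.partitions.csv`.
#'
#' @param path file to read.
#' @param format `"nexus"` or `"csv"` (default guessed from the extension).
#' @param partition_file for CSV input, path of the partition map; ignored
#'   for NEXUS.
#' @param outgroup optional taxon name to record as outgroup.
#' @param strict logical; reject characters absent in every taxon (see
#'   [validate_matrix()]).
#' @return A [character_matrix()].
#' @export
read_matrix <- function(path, format = c("guess", "nexus", "csv"),
                        partition_file = NULL, outgroup = NULL,
                        strict = FALSE) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)
    states <- do.call(rbind, lapply(dat, function(x) {
      x[x %in% c("?", "-")] <- NA
      as.integer(x)
    }))
    rownames(states) <- names(dat)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    labels <- .nexus_charlabels(txt, ncol(states))
    colnames(states) <- labels
    partition <- .nexus_charsets(txt, labels)
  } else {
    tab <- read.csv(path, row.names = 1, check.names = FALSE)
    states <- as.matrix(tab)
    if (is.null(partition_file))
      partition_file <- paste0(path, ".partitions.csv")
    if (file.exists(partition_file)) {
      pm <- read.csv(partition_file, stringsAsFactors = FALSE)
      partition <- setNames(as.character(pm[[2]]), pm[[1]])
      missing_chars <- setdiff(colnames(states), names(partition))
      if (length(missing_chars))
        stop("character without a partition label: ", missing_chars[1])
    } else {
      partition <- "all"
    }
  }
  character_matrix(states, partition = partition, outgroup = outgroup,
                   strict = strict)
}

#' Write a character matrix to NEXUS or CSV
#'
#' The written file round-trips: [read_matrix()] on the output recovers the
#' states, names and partition labels exactly.
#'
#' @param m a [character_matrix()].
#' @param path output file.
#' @param format `"nexus"` or `"csv"`.
#' @param partition_file for CSV, where to write the partition map
#'   (default `<path>.partitions.csv`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("nexus", "csv"),
                         partition_file = NULL) {
  format <- match.arg(format)
  validate_matrix(m)
  s <- m$states
  if (format == "nexus") {
    rows <- apply(s, 1, function(x) {
      x <- as.character(x); x[is.na(x)] <- "?"; paste(x, collapse = "")
    })
    w <- max(nchar(rownames(s)))
    lines <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(s), ncol(s)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
      "  CHARSTATELABELS",
      paste0("    ", paste(sprintf("%d %s", seq_len(ncol(s)), colnames(s)),
                           collapse = ", "), ";"),
      "  MATRIX",
      sprintf("    %-*s  %s", w, rownames(s), rows),
      "  ;",
      "END;",
      "BEGIN SETS;",
      vapply(unique(m$partition), function(l) {
        idx <- which(m$partition == l)
        sprintf("  CHARSET %s = %s;", l, .ranges(idx))
      }, character(1)),
      "END;")
    writeLines(lines, path)
  } else {
    df <- as.data.frame(s, check.names = FALSE)
    write.csv(df, path, row.names = TRUE)
    if (is.null(partition_file))
      partition_file <- paste0(path, ".partitions.csv")
    write.csv(data.frame(character = names(m$partition),
                         partition = unname(m$partition)),
              partition_file, row.names = FALSE)
  }
  invisible(path)
}

## "1-5 7 9-10" style run-length encoding of sorted indices
.ranges <- function(idx) {
  idx <- sort(idx)
  brk <- c(0, which(diff(idx) != 1), length(idx))
  paste(vapply(seq_len(length(brk) - 1), function(i) {
    a <- idx[brk[i] + 1]; b <- idx[brk[i + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = " ")
}

.nexus_charlabels <- function(txt, nchar_expected) {
  m <- regmatches(txt, regexpr("(?is)CHARSTATELABELS\\s+(.*?);", txt,
                               perl = TRUE))
  if (!length(m)) return(paste0("c", seq_len(nchar_expected)))
  body <- sub("(?is)CHARSTATELABELS\\s+", "", m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  items <- strsplit(body, ",")[[1]]
  labs <- vapply(items, function(it) {
    parts <- strsplit(trimws(it), "\\s+")[[1]]
    parts[2]
  }, character(1), USE.NAMES = FALSE)
  if (length(labs) != nchar_expected)
    return(paste0("c", seq_len(nchar_expected)))
  labs
}

.nexus_charsets <- function(txt, labels) {
  hits <- gregexpr("(?i)CHARSET\\s+(\\S+)\\s*=\\s*([-0-9 ]+);", txt,
                   perl = TRUE)[[1]]
  if (hits[1] == -1) return(setNames(rep("all", length(labels)), labels))
  partition <- setNames(rep(NA_character_, length(labels)), labels)
  strs <- regmatches(txt, gregexpr("(?i)CHARSET\\s+\\S+\\s*=\\s*[-0-9 ]+;",
                                   txt, perl = TRUE))[[1]]
  for (s in strs) {
    name <- sub("(?i)CHARSET\\s+(\\S+)\\s*=.*", "\\1", s, perl = TRUE)
    spec <- sub("(?i)CHARSET\\s+\\S+\\s*=\\s*([-0-9 ]+);", "\\1", s,
                perl = TRUE)
    idx <- unlist(lapply(strsplit(trimws(spec), "\\s+")[[1]], function(tok) {
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]]); seq(ab[1], ab[2])
      } else as.integer(tok)
    }))
    partition[idx] <- name
  }
  if (anyNA(partition))
    stop("character without a partition label: ",
         labels[is.na(partition)][1])
  partition
}
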