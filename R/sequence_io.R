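## sequence_io: FASTA I/O, the ReadSet container, and the read-length filter.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Construct a read set
#'
#' A `ReadSet` is the unit all dataset-level comparisons operate on: a labeled,
#' ordered collection of nucleotide reads. Sequences are uppercased on
#' construction; characters outside `A,C,G,T,N` are rejected.
#'
#' @param sequences Named character vector of nucleotide sequences; names are
#'   read ids and must be unique and non-empty.
#' @param label Dataset name (single string).
#' @param descriptions Optional character vector of FASTA descriptions (the
#'   header text after the first whitespace); retained but ignored by all
#'   computations.
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(sequences, label = "reads", descriptions = NULL) {
  if (length(sequences) > 0L) {
    ids <- names(sequences)
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
      stop("every read must have a non-empty id")
    }
    if (anyDuplicated(ids)) {
      stop("duplicate read id: ", ids[duplicated(ids)][1L])
    }
    sequences <- toupper(sequences)
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad)) {
      stop("read '", ids[bad][1L], "' contains characters outside {A,C,G,T,N}")
    }
    if (any(nchar(sequences) < 1L)) {
      stop("read '", ids[nchar(sequences) < 1L][1L], "' has an empty sequence")
    }
  } else {
    sequences <- character(0)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sequences))
  stopifnot(length(descriptions) == length(sequences))
  structure(
    list(label = as.character(label)[1L], sequences = sequences,
         descriptions = unname(descriptions)),
    class = "ReadSet"
  )
}

#' @export
length.ReadSet <- function(x) length(x$sequences)

#' @export
print.ReadSet <- function(x, ...) {
  n <- length(x)
  cat(sprintf("ReadSet '%s': %d reads", x$label, n))
  if (n > 0L) {
    len <- nchar(x$sequences)
    cat(sprintf(", length %d-%d (mean %.1f)", min(len), max(len), mean(len)))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.ReadSet` <- function(x, i) {
  read_set(x$sequences[i], label = x$label, descriptions = x$descriptions[i])
}

#' Read ids of a ReadSet
#' @param rs A `ReadSet`.
#' @return Character vector of read ids, in input order.
#' @export
read_ids <- function(rs) names(rs$sequences)

#' Read lengths of a ReadSet
#' @param rs A `ReadSet`.
#' @return Integer vector of read lengths, in input order.
#' @export
read_lengths <- function(rs) unname(nchar(rs$sequences))

#' Read a FASTA file into a ReadSet
#'
#' The header token before the first whitespace becomes the read id; the
#' remainder is kept as a description. Wrapped and unwrapped FASTA are both
#' accepted. Lowercase bases are uppercased; characters outside `A,C,G,T,N`
#' raise an error naming the offending line.
#'
#' @param path Path to a FASTA file. An empty file yields an empty `ReadSet`.
#' @param label Dataset label; defaults to the file name without extension.
#' @return A `ReadSet`.
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) return(read_set(character(0), label = label))
  if (!startsWith(trimws(lines[content[1L]]), ">")) {
    stop("malformed FASTA in ", path, ": line ", content[1L],
         " is sequence data before any '>' header")
  }
  seq_lines <- content[!startsWith(trimws(lines[content]), ">")]
  bad <- seq_lines[grepl("[^ACGTNacgtn]", trimws(lines[seq_lines]))]
  if (length(bad) > 0L) {
    stop("malformed FASTA in ", path, ": line ", bad[1L],
         " contains characters outside {A,C,G,T,N}")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate read id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("malformed FASTA in ", path, ": record '",
         ids[nchar(seqs) == 0L][1L], "' has an empty sequence")
  }
  names(seqs) <- ids
  read_set(seqs, label = label, descriptions = desc)
}

#' Write a ReadSet to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are reproduced exactly.
#'
#' @param rs A `ReadSet`.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 80); `Inf` writes
#'   each sequence on one line.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(rs, path, width = 80L) {
  stopifnot(inherits(rs, "ReadSet"))
  if (length(rs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(rs$sequences)
  names(set) <- ifelse(nzchar(rs$descriptions),
                       paste(read_ids(rs), rs$descriptions),
                       read_ids(rs))
  w <- if (is.finite(width)) as.integer(width) else 20001L
  Biostrings::writeXStringSet(set, path, width = w)
  invisible(path)
}

#' Discard reads shorter than a minimum length
#'
#' Reads strictly shorter than `min_len` are removed; reads of exactly
#' `min_len` are kept. The default of 60 bp reproduces the pyrosequencing
#' quality-control rule of discarding sequences under 60 bp.
#'
#' @param rs A `ReadSet`.
#' @param min_len Minimum retained read length in bp (default 60).
#' @return A `ReadSet` with the surviving reads, input order preserved.
#' @export
filter_min_length <- function(rs, min_len = 60L) {
  stopifnot(inherits(rs, "ReadSet"))
  if (min_len < 1L) stop("'min_len' must be >= 1")
  keep <- nchar(rs$sequences) >= min_len
  read_set(rs$sequences[keep], label = rs$label,
           descriptions = rs$descriptions[keep])
}
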