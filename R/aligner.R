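## aligner: seed-and-extend local alignment with BLAST-tabular semantics,
## Karlin-Altschul bit scores, and 12-column tabular hit file I/O.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Construct a hit table
#'
#' A `HitTable` is a data frame of local-alignment records in the 12-column
#' BLAST tabular (outfmt 6) column order, the universal currency between the
#' pipeline stages. Minus-strand hits have `sstart > send`.
#'
#' @param hits Data frame with the 12 outfmt-6 columns (`qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore`).
#' @param query_label,subject_label Dataset names the hits relate.
#' @return A `HitTable` (data frame subclass).
#' @export
hit_table <- function(hits = NULL, query_label = "query",
                      subject_label = "subject") {
  if (is.null(hits)) {
    hits <- data.frame(qseqid = character(0), sseqid = character(0),
                       pident = numeric(0), length = integer(0),
                       mismatch = integer(0), gapopen = integer(0),
                       qstart = integer(0), qend = integer(0),
                       sstart = integer(0), send = integer(0),
                       evalue = numeric(0), bitscore = numeric(0),
                       stringsAsFactors = FALSE)
  }
  if (!all(HIT_COLUMNS %in% names(hits))) {
    stop("hit table must have columns: ", paste(HIT_COLUMNS, collapse = " "))
  }
  hits <- as.data.frame(hits)[HIT_COLUMNS]
  if (nrow(hits) > 0L) {
    if (any(hits$qstart > hits$qend)) stop("qstart must be <= qend")
    if (any(hits$length < 1L)) stop("alignment length must be >= 1")
    if (any(hits$pident < 0 | hits$pident > 100)) {
      stop("percent identity must lie in [0, 100]")
    }
    if (any(!is.finite(hits$bitscore))) stop("bit scores must be finite")
  }
  rownames(hits) <- NULL
  structure(hits, class = c("HitTable", "data.frame"),
            query_label = query_label, subject_label = subject_label)
}

#' @export
print.HitTable <- function(x, ...) {
  cat(sprintf("HitTable %s vs %s: %d hits\n", attr(x, "query_label"),
              attr(x, "subject_label"), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 10L), ...)
  invisible(x)
}

#' Default alignment parameters
#'
#' Scoring follows common ungapped nucleotide defaults: match +1, mismatch -2,
#' with Karlin-Altschul parameters `lambda` = 1.28 and `K` = 0.46 applied to
#' the raw scores. Downstream bit-score Jaccard distances are invariant to
#' uniform bit-score rescaling, so these defaults affect nothing structural.
#'
#' @param k Seed (word) length, >= 8.
#' @param match,mismatch Match reward (positive) and mismatch penalty
#'   (negative).
#' @param xdrop X-drop threshold in raw score units for ungapped extension.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @param max_evalue Hits with larger e-value are not reported.
#' @param best_per_pair If `TRUE` (default) report one best-scoring HSP per
#'   (query, subject) pair; if `FALSE` report all HSPs.
#' @return A list of alignment parameters for [find_hits()].
#' @export
alignment_params <- function(k = 11L, match = 1L, mismatch = -2L, xdrop = 20,
                             lambda = 1.28, K = 0.46, max_evalue = 10,
                             best_per_pair = TRUE) {
  if (k < 8L) stop("seed length 'k' must be >= 8")
  if (match <= 0L || mismatch >= 0L) {
    stop("'match' must be positive and 'mismatch' negative")
  }
  if (lambda <= 0 || K <= 0) stop("'lambda' and 'K' must be positive")
  list(k = as.integer(k), match = as.integer(match),
       mismatch = as.integer(mismatch), xdrop = xdrop, lambda = lambda,
       K = K, max_evalue = max_evalue, best_per_pair = isTRUE(best_per_pair))
}

#' Align a read set against a sequence collection
#'
#' Exact k-mer seeding on both strands followed by ungapped X-drop extension;
#' raw scores are converted to bits with the Karlin-Altschul formula and
#' e-values computed over the total subject length. Identity is
#' `100 * matches / alignment length`. By default one best-scoring HSP per
#' (query, subject) pair is reported.
#'
#' @param query A `ReadSet` of query reads.
#' @param subject A `ReadSet`, or a named character vector of subject
#'   sequences (e.g. reference genomes).
#' @param params Alignment parameters from [alignment_params()].
#' @return A `HitTable`.
#' @export
find_hits <- function(query, subject, params = alignment_params()) {
  stopifnot(inherits(query, "ReadSet"))
  if (inherits(subject, "ReadSet")) {
    subj_seqs <- subject$sequences
    subj_label <- subject$label
  } else if (is.character(subject) && !is.null(names(subject))) {
    subj_seqs <- subject
    subj_label <- "subject"
  } else {
    stop("'subject' must be a ReadSet or a named character vector")
  }
  if (length(subj_seqs) == 0L) stop("empty subject collection")
  if (length(query) == 0L) {
    return(hit_table(NULL, query$label, subj_label))
  }
  df <- .align_sets(query$sequences, subj_seqs, params$k, params$match,
                    params$mismatch, params$xdrop, params$lambda, params$K,
                    params$max_evalue, params$best_per_pair)
  hit_table(df, query_label = query$label, subject_label = subj_label)
}

#' Karlin-Altschul bit score
#'
#' Normalizes a raw alignment score into bits:
#' `(lambda * raw_score - ln K) / ln 2`.
#'
#' @param raw_score Raw alignment score(s).
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, lambda = 1.28, K = 0.46) {
  if (any(lambda <= 0) || any(K <= 0)) {
    stop("'lambda' and 'K' must be positive")
  }
  (lambda * raw_score - log(K)) / log(2)
}

#' Alignment e-value from a bit score
#'
#' `E = m * n * 2^(-bit_score)` for query length `m` and subject search-space
#' size `n`.
#'
#' @param bit_score Bit score(s).
#' @param m Query length in bp (>= 1).
#' @param n Subject search-space size in bp (>= 1).
#' @return Expected number of chance hits at this score.
#' @export
evalue <- function(bit_score, m, n) {
  if (any(m < 1) || any(n < 1)) stop("'m' and 'n' must be >= 1")
  m * n * 2^(-bit_score)
}

#' Read a 12-column tabular hit file
#'
#' BLAST outfmt-6 column order; lines starting with `#` are skipped;
#' scientific-notation e-values are parsed. This is the ingestion point for
#' hits produced by external aligners.
#'
#' @param path Path to a tab-separated hit file.
#' @param query_label,subject_label Dataset names to attach.
#' @return A `HitTable`.
#' @export
read_tabular_hits <- function(path, query_label = "query",
                              subject_label = "subject") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) return(hit_table(NULL, query_label, subject_label))
  kept_line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- kept_line_no[nf != 12L][1L]
    stop("parse error in ", path, " line ", bad, ": expected 12 tab-separated",
         " columns, found ", nf[nf != 12L][1L])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  hit_table(df, query_label, subject_label)
}

#' Write a hit table as 12-column tabular
#'
#' Lossless round trip with [read_tabular_hits()].
#'
#' @param ht A `HitTable`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tabular_hits <- function(ht, path) {
  stopifnot(inherits(ht, "HitTable"))
  df <- as.data.frame(ht)
  df$pident <- formatC(df$pident, format = "fg", digits = 15)
  df$evalue <- formatC(df$evalue, format = "g", digits = 15)
  df$bitscore <- formatC(df$bitscore, format = "fg", digits = 15)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
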