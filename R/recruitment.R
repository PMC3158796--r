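## recruitment: fragment recruitment of reads against reference genomes,
## genome ranking by recruited reads, and the dataset-overlap fraction.

#' Recruit reads to a reference genome
#'
#' Retains hits with percent identity at least `min_identity` and alignment
#' length at least `min_len` (both inclusive; the defaults are the standard
#' recruitment criteria of 95% identity and 50 bp), keeps only each read's
#' best-scoring hit, and reports one point per recruited read at the
#' subject-coordinate midpoint.
#'
#' @param ht A `HitTable` of reads against a single genome.
#' @param genome_length Genome length in bp; must cover every subject
#'   coordinate in the table.
#' @param min_identity Minimum percent identity (inclusive, default 95).
#' @param min_len Minimum alignment length in bp (inclusive, default 50).
#' @param genome_id Genome identifier for the result (defaults to the
#'   table's subject label).
#' @return A `RecruitmentResult`: list with `genome_id`, `points` (data
#'   frame of `position`, `identity`, `read_id`), `n_recruited`,
#'   `genome_length`.
#' @export
recruit <- function(ht, genome_length, min_identity = 95, min_len = 50,
                    genome_id = NULL) {
  stopifnot(inherits(ht, "HitTable"))
  if (is.null(genome_id)) genome_id <- attr(ht, "subject_label")
  if (nrow(ht) > 0L && genome_length < max(ht$sstart, ht$send)) {
    stop("'genome_length' smaller than the largest subject coordinate")
  }
  keep <- ht$pident >= min_identity & ht$length >= min_len
  df <- as.data.frame(ht)[keep, , drop = FALSE]
  if (nrow(df) > 0L) {
    ## best hit per read; ties broken by higher identity then input order
    ord <- order(df$qseqid, -df$bitscore, -df$pident)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$qseqid), , drop = FALSE]
    lo <- pmin(df$sstart, df$send)
    hi <- pmax(df$sstart, df$send)
    points <- data.frame(position = as.integer(lo + (hi - lo) %/% 2),
                         identity = df$pident,
                         read_id = df$qseqid,
                         stringsAsFactors = FALSE)
    points <- points[order(points$position, points$read_id), , drop = FALSE]
    rownames(points) <- NULL
  } else {
    points <- data.frame(position = integer(0), identity = numeric(0),
                         read_id = character(0), stringsAsFactors = FALSE)
  }
  structure(list(genome_id = genome_id, points = points,
                 n_recruited = nrow(points), genome_length = genome_length),
            class = "RecruitmentResult")
}

#' @export
print.RecruitmentResult <- function(x, ...) {
  cat(sprintf("RecruitmentResult '%s': %d reads over %d bp\n", x$genome_id,
              x$n_recruited, x$genome_length))
  invisible(x)
}

#' Rank genomes by recruited reads
#'
#' @param results List of `RecruitmentResult` objects (at least one).
#' @return Data frame `(genome_id, n_recruited)` sorted by descending count,
#'   ties broken by genome id.
#' @export
rank_genomes <- function(results) {
  if (length(results) < 1L) stop("at least one RecruitmentResult is required")
  stopifnot(all(vapply(results, inherits, logical(1L), "RecruitmentResult")))
  df <- data.frame(
    genome_id = vapply(results, `[[`, character(1L), "genome_id"),
    n_recruited = vapply(results, function(r) as.integer(r$n_recruited),
                         integer(1L)),
    stringsAsFactors = FALSE)
  df <- df[order(-df$n_recruited, df$genome_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Fraction of query reads covered by another dataset
#'
#' The fraction of distinct query reads having at least one hit with percent
#' identity strictly above `min_identity` and query coverage
#' `(qend - qstart + 1) / read length` of at least `min_query_cov`. With the
#' defaults (>90% identity, 50% coverage) this is the criterion used to ask
#' how much of one metagenome overlaps another.
#'
#' @param queries The query `ReadSet`.
#' @param ht A `HitTable` whose queries are drawn from `queries`.
#' @param min_identity Identity threshold in percent (strict, default 90).
#' @param min_query_cov Minimum query coverage fraction (inclusive,
#'   default 0.5).
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(queries, ht, min_identity = 90,
                             min_query_cov = 0.5) {
  stopifnot(inherits(queries, "ReadSet"), inherits(ht, "HitTable"))
  if (length(queries) == 0L) stop("empty query ReadSet")
  if (nrow(ht) == 0L) return(0)
  unknown <- setdiff(unique(ht$qseqid), read_ids(queries))
  if (length(unknown) > 0L) {
    stop("hit query id absent from the ReadSet: ", unknown[1L])
  }
  qlen <- setNames(read_lengths(queries), read_ids(queries))
  cov <- (ht$qend - ht$qstart + 1) / qlen[ht$qseqid]
  ok <- ht$pident > min_identity & cov >= min_query_cov
  length(unique(ht$qseqid[ok])) / length(queries)
}

#' Write recruitment points as TSV
#'
#' Columns `position`, `identity`, `read_id`; consumable by any plotting
#' layer.
#'
#' @param result A `RecruitmentResult`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recruitment <- function(result, path) {
  stopifnot(inherits(result, "RecruitmentResult"))
  write.table(result$points, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot a fragment recruitment result
#'
#' Scatter of alignment midpoint along the genome against percent identity.
#'
#' @param x A `RecruitmentResult`.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.RecruitmentResult <- function(x, ...) {
  plot(x$points$position, x$points$identity, pch = 16, cex = 0.4,
       xlim = c(1, x$genome_length), ylim = c(min(80, x$points$identity), 100),
       xlab = sprintf("position on %s (bp)", x$genome_id),
       ylab = "% identity", main = sprintf("%d reads recruited",
                                           x$n_recruited), ...)
  invisible(x)
}
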