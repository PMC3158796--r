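## taxonomy: identity-threshold classification of rRNA gene fragments,
## simplified best-hit binning of bulk reads, and profile aggregation.

#' Construct taxon assignments
#'
#' @param read_id,taxon,rank,best_identity,note Parallel vectors; `rank` is
#'   one of `"genus"`, `"higher"`, `"unidentified"`.
#' @return A `TaxonAssignment` data frame.
#' @keywords internal
taxon_assignment <- function(read_id, taxon, rank, best_identity, note) {
  stopifnot(all(rank %in% c("genus", "higher", "unidentified")))
  df <- data.frame(read_id = read_id, taxon = taxon, rank = rank,
                   best_identity = best_identity, note = note,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("TaxonAssignment", "data.frame")
  df
}

ref_is_named <- function(refs) {
  !grepl("uncultured|unidentified", refs$annotation, ignore.case = TRUE) &
    !is.na(refs$genus)
}

#' Classify rRNA gene fragments by identity thresholds
#'
#' Implements the standard rule ladder for read-level small-subunit rRNA
#' identification against a reference collection: alignments of 100 bp or
#' less are discarded; among the surviving hits to *named* references (those
#' not annotated "uncultured"/"unidentified") the best-scoring one is taken;
#' identity strictly above 95% assigns the record's genus, identity in
#' `[90, 95]` assigns only its higher taxon, and identity below 90% -- or
#' hits only to uncultured/unidentified records, or no hits at all -- leaves
#' the read unidentified.
#'
#' @param read_hits A `HitTable` of reads against the reference collection.
#' @param refs A `ReferenceSet` (data frame with `id`, `genus`,
#'   `higher_taxon`, `annotation`), covering every subject id in the hits.
#' @param read_ids Optional character vector of all read ids to classify;
#'   defaults to the ids present in `read_hits`. Reads without hits are
#'   reported as unidentified.
#' @param min_len Alignment length that hits must strictly exceed
#'   (default 100 bp).
#' @param genus_identity Identity strictly above this assigns genus
#'   (default 95).
#' @param unidentified_below Identity strictly below this is unidentified
#'   (default 90).
#' @return A `TaxonAssignment` data frame, one row per read.
#' @export
classify_rrna <- function(read_hits, refs, read_ids = NULL, min_len = 100,
                          genus_identity = 95, unidentified_below = 90) {
  stopifnot(inherits(read_hits, "HitTable"), is.data.frame(refs))
  missing_ref <- setdiff(unique(read_hits$sseqid), refs$id)
  if (length(missing_ref) > 0L) {
    stop("reference id in hits missing from refs: ", missing_ref[1L])
  }
  if (is.null(read_ids)) read_ids <- unique(read_hits$qseqid)
  named <- setNames(ref_is_named(refs), refs$id)
  genus <- setNames(refs$genus, refs$id)
  higher <- setNames(refs$higher_taxon, refs$id)
  ht <- as.data.frame(read_hits)
  ht <- ht[ht$length > min_len, , drop = FALSE]
  one <- function(rid) {
    h <- ht[ht$qseqid == rid, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(list(taxon = "unidentified", rank = "unidentified",
                  identity = NA_real_, note = "no qualifying hit"))
    }
    hn <- h[named[h$sseqid], , drop = FALSE]
    if (nrow(hn) == 0L) {
      return(list(taxon = "unidentified", rank = "unidentified",
                  identity = max(h$pident),
                  note = "only uncultured/unidentified matches"))
    }
    best <- hn[order(-hn$bitscore, -hn$pident, hn$sseqid), , drop = FALSE][1L, ]
    if (best$pident > genus_identity) {
      list(taxon = genus[[best$sseqid]], rank = "genus",
           identity = best$pident, note = paste0("best named hit ",
                                                 best$sseqid))
    } else if (best$pident >= unidentified_below) {
      list(taxon = higher[[best$sseqid]], rank = "higher",
           identity = best$pident, note = paste0("best named hit ",
                                                 best$sseqid))
    } else {
      list(taxon = "unidentified", rank = "unidentified",
           identity = best$pident, note = "best named hit below 90% identity")
    }
  }
  out <- lapply(read_ids, one)
  taxon_assignment(read_ids,
                   vapply(out, `[[`, character(1L), "taxon"),
                   vapply(out, `[[`, character(1L), "rank"),
                   vapply(out, `[[`, numeric(1L), "identity"),
                   vapply(out, `[[`, character(1L), "note"))
}

#' Bin bulk reads to taxa by best hit
#'
#' Each read is assigned the taxon of the reference genome holding its
#' best-scoring hit among hits passing the e-value and alignment-length
#' cutoffs (defaults: e-value at most 1e-5, length at least 50 bp). Reads
#' with no passing hit are unclassified. Bit-score ties are broken by
#' ascending subject id.
#'
#' @param ht A `HitTable` of reads against reference genomes.
#' @param genome_taxa Named character vector mapping every subject id to a
#'   taxon.
#' @param read_ids Optional full set of read ids; defaults to the ids in
#'   `ht`.
#' @param max_evalue Maximum e-value (inclusive, default 1e-5).
#' @param min_len Minimum alignment length in bp (inclusive, default 50).
#' @return A `TaxonAssignment` data frame with rank `"higher"` for binned
#'   reads and `"unidentified"` for unclassified ones.
#' @export
bin_reads_best_hit <- function(ht, genome_taxa, read_ids = NULL,
                               max_evalue = 1e-5, min_len = 50) {
  stopifnot(inherits(ht, "HitTable"))
  missing_tax <- setdiff(unique(ht$sseqid), names(genome_taxa))
  if (length(missing_tax) > 0L) {
    stop("subject id without a taxon mapping: ", missing_tax[1L])
  }
  if (is.null(read_ids)) read_ids <- unique(ht$qseqid)
  df <- as.data.frame(ht)
  df <- df[df$evalue <= max_evalue & df$length >= min_len, , drop = FALSE]
  if (nrow(df) > 0L) {
    df <- df[order(df$qseqid, -df$bitscore, df$sseqid), , drop = FALSE]
    df <- df[!duplicated(df$qseqid), , drop = FALSE]
  }
  best <- setNames(df$sseqid, df$qseqid)
  bid <- setNames(df$pident, df$qseqid)
  has <- read_ids %in% names(best)
  taxon_assignment(
    read_ids,
    ifelse(has, unname(genome_taxa[best[read_ids]]), "unclassified"),
    ifelse(has, "higher", "unidentified"),
    ifelse(has, unname(bid[read_ids]), NA_real_),
    ifelse(has, paste0("best hit ", unname(best[read_ids])),
           "no passing hit"))
}

#' Aggregate taxon assignments into a composition profile
#'
#' @param assignments A `TaxonAssignment` data frame.
#' @return A `ProfileTable` data frame with one row per taxon plus an
#'   `unclassified` row: columns `taxon`, `count`, `percent_classified`
#'   (of classified reads; `NA` for the unclassified row) and
#'   `percent_total`. Rows are ordered by descending count, the unclassified
#'   row last.
#' @export
taxon_profile <- function(assignments) {
  stopifnot(inherits(assignments, "TaxonAssignment"))
  n <- nrow(assignments)
  if (n == 0L) {
    out <- data.frame(taxon = "unclassified", count = 0L,
                      percent_classified = NA_real_, percent_total = 0,
                      stringsAsFactors = FALSE)
    class(out) <- c("ProfileTable", "data.frame")
    return(out)
  }
  classified <- assignments$rank != "unidentified"
  tab <- table(assignments$taxon[classified])
  n_cls <- sum(classified)
  df <- data.frame(taxon = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$taxon), , drop = FALSE]
  df$percent_classified <- if (n_cls > 0) 100 * df$count / n_cls else
    numeric(nrow(df))
  df$percent_total <- 100 * df$count / n
  out <- rbind(df,
               data.frame(taxon = "unclassified",
                          count = n - n_cls,
                          percent_classified = NA_real_,
                          percent_total = 100 * (n - n_cls) / n,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("ProfileTable", "data.frame")
  out
}

#' Write a reference collection as FASTA with structured headers
#'
#' Header layout: `id|genus|higher_taxon|annotation` (empty genus for
#' uncultured entries); parsed back by [read_reference_fasta()].
#'
#' @param refs A `ReferenceSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(refs, path) {
  hdr <- sprintf("%s|%s|%s|%s", refs$id,
                 ifelse(is.na(refs$genus), "", refs$genus),
                 refs$higher_taxon, refs$annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", hdr, "\n", refs$sequence), con, sep = "\n")
  invisible(path)
}

#' Read a structured-header reference FASTA
#'
#' @param path Path written by [write_reference_fasta()].
#' @return A `ReferenceSet` data frame.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("reference header without 4 '|'-separated fields: ",
         names(set)[bad][1L])
  }
  m <- do.call(rbind, parts)
  refs <- data.frame(id = m[, 1L], sequence = as.character(set),
                     genus = ifelse(nzchar(m[, 2L]), m[, 2L], NA_character_),
                     higher_taxon = m[, 3L], annotation = m[, 4L],
                     stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  class(refs) <- c("ReferenceSet", "data.frame")
  refs
}
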