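## dataset_distance: bit-score Jaccard distances between whole read datasets,
## distance matrices from all-vs-all alignment, and neighbor-joining trees.

#' Apply the dataset-comparison hit filter
#'
#' Retains hits with percent identity strictly above `min_identity` and
#' alignment length strictly above `min_len`. The defaults (>70% identity,
#' >100 bp) are the whole-dataset comparison criteria; both inequalities are
#' strict.
#'
#' @param ht A `HitTable`.
#' @param min_identity Identity threshold in percent (default 70).
#' @param min_len Alignment-length threshold in bp (default 100).
#' @return A filtered `HitTable`.
#' @export
filter_distance_hits <- function(ht, min_identity = 70, min_len = 100) {
  stopifnot(inherits(ht, "HitTable"))
  if (min_identity < 0 || min_len < 0) stop("thresholds must be non-negative")
  keep <- ht$pident > min_identity & ht$length > min_len
  hit_table(as.data.frame(ht)[keep, , drop = FALSE],
            attr(ht, "query_label"), attr(ht, "subject_label"))
}

#' Total bit score of a hit table
#'
#' Sums bit scores under a hit-selection policy: `best-per-query` (default)
#' takes each query's single best-scoring hit, `best-per-pair` each
#' (query, subject) pair's best, and `all-hsps` every record.
#'
#' @param ht A `HitTable`, already filtered as desired.
#' @param policy One of `"best-per-query"`, `"best-per-pair"`, `"all-hsps"`.
#' @return Total bit score (0 for an empty table).
#' @export
total_bit_score <- function(ht, policy = c("best-per-query", "best-per-pair",
                                           "all-hsps")) {
  stopifnot(inherits(ht, "HitTable"))
  policy <- match.arg(policy)
  if (nrow(ht) == 0L) return(0)
  switch(policy,
    "best-per-query" = sum(tapply(ht$bitscore, ht$qseqid, max)),
    "best-per-pair" = sum(tapply(ht$bitscore,
                                 paste(ht$qseqid, ht$sseqid, sep = "\r"),
                                 max)),
    "all-hsps" = sum(ht$bitscore))
}

#' Bit-score Jaccard distance between two datasets
#'
#' For total bit scores `AA_s` and `BB_s` of each dataset aligned to itself
#' and `AB_s` of the cross-comparison, the Jaccard distance is
#' `D = 1 - AB_s / (AA_s + BB_s - AB_s)`: one minus shared bit-score mass
#' over union bit-score mass. A Sorensen-Dice variant
#' `1 - 2 AB_s / (AA_s + BB_s)` is available via `form`.
#'
#' @param AB_s Total bit score of the common hits between the datasets.
#' @param AA_s,BB_s Total self-comparison bit scores (both > 0).
#' @param form `"jaccard"` (default) or `"dice"`.
#' @return A distance in `[0, 1]`.
#' @export
jaccard_distance <- function(AB_s, AA_s, BB_s, form = c("jaccard", "dice")) {
  form <- match.arg(form)
  if (AA_s <= 0 || BB_s <= 0) stop("self scores must be positive")
  if (AB_s < 0) stop("'AB_s' must be non-negative")
  if (AB_s > min(AA_s, BB_s) + 1e-9 * min(AA_s, BB_s)) {
    stop("inconsistent inputs: AB_s exceeds min(AA_s, BB_s)")
  }
  d <- switch(form,
              jaccard = 1 - AB_s / (AA_s + BB_s - AB_s),
              dice = 1 - 2 * AB_s / (AA_s + BB_s))
  min(max(d, 0), 1)
}

#' All-vs-all bit-score Jaccard distance matrix
#'
#' For every pair of datasets, reads are aligned in both directions and each
#' dataset against itself (self-hits included by default), hits are filtered
#' with [filter_distance_hits()], total bit scores taken under `policy`, the
#' cross score symmetrized as `(A->B + B->A) / 2`, and [jaccard_distance()]
#' applied.
#'
#' @param datasets List of at least two `ReadSet`s with unique labels.
#' @param params Alignment parameters from [alignment_params()].
#' @param min_identity,min_len Hit filter thresholds (see
#'   [filter_distance_hits()]).
#' @param policy Bit-score totaling policy (see [total_bit_score()]).
#' @param form Distance form (see [jaccard_distance()]).
#' @param include_self_hits Keep each read's hit to itself in the
#'   self-comparison totals (default `TRUE`).
#' @return A `DistanceMatrix`: symmetric numeric matrix with zero diagonal,
#'   labeled by dataset.
#' @export
distance_matrix <- function(datasets, params = alignment_params(),
                            min_identity = 70, min_len = 100,
                            policy = "best-per-query", form = "jaccard",
                            include_self_hits = TRUE) {
  if (length(datasets) < 2L) stop("at least two datasets are required")
  stopifnot(all(vapply(datasets, inherits, logical(1L), "ReadSet")))
  labels <- vapply(datasets, function(d) d$label, character(1L))
  if (anyDuplicated(labels)) stop("dataset labels must be unique")
  n <- length(datasets)
  score_of <- function(ht) {
    total_bit_score(filter_distance_hits(ht, min_identity, min_len), policy)
  }
  self_scores <- vapply(seq_len(n), function(i) {
    ht <- find_hits(datasets[[i]], datasets[[i]], params)
    if (!include_self_hits) {
      ht <- hit_table(as.data.frame(ht)[ht$qseqid != ht$sseqid, ,
                                        drop = FALSE],
                      attr(ht, "query_label"), attr(ht, "subject_label"))
    }
    score_of(ht)
  }, numeric(1L))
  if (any(self_scores <= 0)) {
    stop("dataset '", labels[self_scores <= 0][1L],
         "' has zero post-filter self score; distance undefined")
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ab <- score_of(find_hits(datasets[[i]], datasets[[j]], params))
      ba <- score_of(find_hits(datasets[[j]], datasets[[i]], params))
      cross <- (ab + ba) / 2
      cross <- min(cross, self_scores[i], self_scores[j])
      d <- jaccard_distance(cross, self_scores[i], self_scores[j],
                            form = form)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(m, class = c("DistanceMatrix", class(m)))
}

#' @export
print.DistanceMatrix <- function(x, digits = 4, ...) {
  cat("Bit-score Jaccard distance matrix (", nrow(x), " datasets)\n",
      sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

check_square_symmetric <- function(dm) {
  m <- unclass(dm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix not square")
  if (is.null(rownames(m))) stop("distance matrix must be labeled")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be 0")
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (as in PHYLIP's `neighbor`); negative branch
#' lengths arising from non-additive matrices are clamped to zero. On an
#' additive matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param dm A `DistanceMatrix` (or labeled symmetric matrix) over at least
#'   three datasets.
#' @return An unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(dm) {
  m <- check_square_symmetric(dm)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 labels")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Write a tree as Newick, optionally rooted on an outgroup
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @param outgroup Optional leaf label; the tree is rooted on its pendant
#'   edge before writing.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("unknown outgroup label: ", outgroup)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as labeled square TSV
#'
#' @param dm A `DistanceMatrix`.
#' @param path Output path.
#' @param lower_triangle Also acceptable: write a PHYLIP-style lower-triangle
#'   file instead of the square layout.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, lower_triangle = FALSE) {
  m <- check_square_symmetric(dm)
  if (lower_triangle) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      vals <- if (i > 1L) paste(sprintf("%.6f", m[i, 1:(i - 1L)]),
                                collapse = "  ") else ""
      writeLines(trimws(sprintf("%-12s %s", rownames(m)[i], vals),
                        which = "right"), con)
    }
  } else {
    df <- data.frame(dataset = rownames(m), round(m, 10),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a square labeled distance-matrix TSV
#'
#' @param path Path written by [write_distance_matrix()] (square layout).
#' @return A `DistanceMatrix`.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  structure(m, class = c("DistanceMatrix", class(m)))
}
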