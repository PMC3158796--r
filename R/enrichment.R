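## enrichment: functional-profile comparison (two-sided Fisher's exact test,
## Storey q-values, three-way significance/abundance/effect filter) and the
## protein-domain abundance ratio.

#' Construct a category-count table
#'
#' @param counts Named non-negative integer vector (names are category ids),
#'   or a two-column data frame `(category, count)`.
#' @param label Dataset label.
#' @return A `CategoryCounts` data frame with attributes `label` and
#'   `total`.
#' @export
category_counts <- function(counts, label = "dataset") {
  if (is.data.frame(counts)) {
    stopifnot(ncol(counts) >= 2L)
    counts <- setNames(counts[[2L]], as.character(counts[[1L]]))
  }
  if (is.null(names(counts)) || anyDuplicated(names(counts))) {
    stop("categories must be uniquely named")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  df <- data.frame(category = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("CategoryCounts", "data.frame"),
            label = label, total = sum(df$count))
}

#' @export
print.CategoryCounts <- function(x, ...) {
  cat(sprintf("CategoryCounts '%s': %d categories, %d sequences\n",
              attr(x, "label"), nrow(x), attr(x, "total")))
  invisible(x)
}

#' Read a two-column category-count TSV
#'
#' Format: `category<TAB>count`, one row per category, optional header.
#'
#' @param path Input path.
#' @param label Dataset label (defaults to the file name).
#' @return A `CategoryCounts`.
#' @export
read_category_counts <- function(path, label = NULL) {
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1L, 2L])))) {
    df <- df[-1L, , drop = FALSE] # header row
  }
  category_counts(setNames(as.integer(df[[2L]]), df[[1L]]), label = label)
}

#' Write a category-count table as two-column TSV
#'
#' @param cc A `CategoryCounts`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_category_counts <- function(cc, path) {
  stopifnot(inherits(cc, "CategoryCounts"))
  write.table(as.data.frame(cc), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value obtained by summing the
#' probabilities of all tables with the same margins whose point probability
#' does not exceed the observed one (with a small relative slack for
#' floating-point ties). Table layout: `(a, b)` in row one, `(c, d)` in row
#' two.
#'
#' @param a,b,c,d Non-negative cell counts; both margins must be positive.
#' @return The two-sided p-value.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("both margins must be positive")
  }
  min(1, fisher.test(matrix(c(a, c, b, d), 2L),
                     alternative = "two.sided")$p.value)
}

#' Storey q-values
#'
#' The proportion of true nulls is estimated at a single tuning point as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))` and q-values are the
#' monotone step-up transform `q_(i) = min_(j >= i) pi0 m p_(j) / j` over the
#' sorted p-values, mapped back to input order. With `pi0` pinned to 1 this
#' reduces exactly to the Benjamini-Hochberg adjustment.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (non-empty).
#' @param lambda Tuning point for the `pi0` estimate (default 0.5).
#' @param pi0 Optional override for the null proportion (e.g. `1` for plain
#'   Benjamini-Hochberg behavior).
#' @return Numeric vector of q-values in input order.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5, pi0 = NULL) {
  if (length(pvalues) == 0L) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
    if (pi0 <= 0) pi0 <- 1 / m # all p tiny: keep q-values positive
  }
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  q_sorted <- pi0 * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Compare two functional profiles
#'
#' For each category of the shared universe (absent categories imputed count
#' 0) a 2x2 table of the category count against the rest of each dataset is
#' tested with the two-sided Fisher's exact test; q-values are computed over
#' all categories with [storey_qvalues()]. A category passes when
#' `q <= q_max`, its combined count reaches `min_seqs` (or each dataset's
#' count when `per_dataset = TRUE`) and the fold ratio between its
#' proportions strictly exceeds `min_ratio`. Proportion ratios involving a
#' zero count use a pseudocount of 0.5 on the zero cell only.
#'
#' @param A,B `CategoryCounts` tables with positive totals.
#' @param q_max Q-value cutoff (default 0.05).
#' @param min_seqs Minimum sequence count (default 100).
#' @param min_ratio Fold-ratio threshold, strict (default 2).
#' @param per_dataset Require `min_seqs` in each dataset instead of combined
#'   (default `FALSE`).
#' @return An `EnrichmentTable` data frame with columns `category`,
#'   `countA`, `countB`, `propA`, `propB`, `ratio`, `p`, `q`, `passes`,
#'   sorted by ascending q then p.
#' @export
compare_profiles <- function(A, B, q_max = 0.05, min_seqs = 100,
                             min_ratio = 2, per_dataset = FALSE) {
  stopifnot(inherits(A, "CategoryCounts"), inherits(B, "CategoryCounts"))
  totalA <- attr(A, "total"); totalB <- attr(B, "total")
  if (totalA == 0 || totalB == 0) stop("profile totals must be positive")
  cats <- union(A$category, B$category)
  ca <- setNames(rep(0L, length(cats)), cats)
  cb <- ca
  ca[A$category] <- A$count
  cb[B$category] <- B$count
  propA <- ca / totalA
  propB <- cb / totalB
  ## pseudocount on zero cells only, for the ratio
  ra <- ifelse(ca == 0, 0.5, ca) / totalA
  rb <- ifelse(cb == 0, 0.5, cb) / totalB
  ratio <- pmax(ra / rb, rb / ra)
  p <- vapply(seq_along(cats), function(i) {
    fisher_two_sided(ca[i], totalA - ca[i], cb[i], totalB - cb[i])
  }, numeric(1L))
  q <- storey_qvalues(p)
  abundant <- if (per_dataset) ca >= min_seqs & cb >= min_seqs else
    (ca + cb) >= min_seqs
  out <- data.frame(category = cats, countA = unname(ca),
                    countB = unname(cb), propA = unname(propA),
                    propB = unname(propB), ratio = unname(ratio),
                    p = p, q = q,
                    passes = q <= q_max & abundant & ratio > min_ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Protein-domain abundance ratio between two datasets
#'
#' For each domain, `ratio = (countX / totalX) / (countY / totalY)` -- the
#' percentage of the domain in dataset X over its percentage in dataset Y. A
#' pseudocount (default 0.5) replaces zero counts only, and such rows are
#' flagged.
#'
#' @param X,Y `CategoryCounts` tables of domain counts with positive totals.
#' @param pseudocount Value substituted for zero counts (default 0.5).
#' @return Data frame `(category, countX, countY, ratio, pseudocounted)`
#'   sorted by descending ratio.
#' @export
domain_abundance_ratio <- function(X, Y, pseudocount = 0.5) {
  stopifnot(inherits(X, "CategoryCounts"), inherits(Y, "CategoryCounts"))
  totalX <- attr(X, "total"); totalY <- attr(Y, "total")
  if (totalX == 0 || totalY == 0) stop("domain totals must be positive")
  cats <- union(X$category, Y$category)
  cx <- setNames(rep(0L, length(cats)), cats)
  cy <- cx
  cx[X$category] <- X$count
  cy[Y$category] <- Y$count
  flag <- cx == 0 | cy == 0
  nx <- ifelse(cx == 0, pseudocount, cx)
  ny <- ifelse(cy == 0, pseudocount, cy)
  out <- data.frame(category = cats, countX = unname(cx), countY = unname(cy),
                    ratio = unname((nx / totalX) / (ny / totalY)),
                    pseudocounted = unname(flag), stringsAsFactors = FALSE)
  out <- out[order(-out$ratio, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param et An `EnrichmentTable` from [compare_profiles()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(et, path) {
  stopifnot(inherits(et, "EnrichmentTable"))
  df <- as.data.frame(et)
  for (col in c("propA", "propB", "ratio", "p", "q")) {
    df[[col]] <- formatC(df[[col]], format = "g", digits = 10)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
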