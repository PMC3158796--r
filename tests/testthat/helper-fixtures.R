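## Shared fixtures and independent oracles, all built in code.

## A hit-table data frame from minimal per-hit information.
make_hits <- function(qseqid, sseqid = "s1", pident = 100, length = 200,
                      bitscore = length, evalue = 1e-10, qstart = 1,
                      qend = qstart + length - 1, sstart = 1,
                      send = sstart + length - 1) {
  n <- max(lengths(list(qseqid, sseqid, pident, length, bitscore)))
  df <- data.frame(qseqid = rep_len(qseqid, n), sseqid = rep_len(sseqid, n),
                   pident = rep_len(pident, n), length = rep_len(length, n),
                   mismatch = 0L, gapopen = 0L,
                   qstart = rep_len(qstart, n), qend = rep_len(qend, n),
                   sstart = rep_len(sstart, n), send = rep_len(send, n),
                   evalue = rep_len(evalue, n),
                   bitscore = rep_len(bitscore, n),
                   stringsAsFactors = FALSE)
  hit_table(df)
}

## A random hit table for brute-force comparison properties.
random_hits <- function(n, n_queries = 10, n_subjects = 4, seed = 1) {
  set.seed(seed)
  len <- sample(30:400, n, replace = TRUE)
  st <- sample(1:5000, n, replace = TRUE)
  make_hits(qseqid = sprintf("q%02d", sample.int(n_queries, n, TRUE)),
            sseqid = sprintf("s%02d", sample.int(n_subjects, n, TRUE)),
            pident = round(runif(n, 40, 100), 2),
            length = len,
            bitscore = round(runif(n, 20, 500), 1),
            evalue = 10^runif(n, -30, 0),
            qstart = 1, qend = len, sstart = st, send = st + len - 1)
}

## Independent two-sided Fisher oracle: full hypergeometric enumeration.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Deterministic random nucleotide sequence.
random_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## A tiny rRNA reference collection with named and uncultured entries.
ref_fixture <- function() {
  refs <- data.frame(
    id = c("ref_named1", "ref_named2", "ref_unc"),
    sequence = c("ACGT", "ACGT", "ACGT"),
    genus = c("Polynucleobacter", "Nitrosopumilus", NA),
    higher_taxon = c("Betaproteobacteria", "Crenarchaeota", "Bacteria"),
    annotation = c("Polynucleobacter sp. rRNA", "Nitrosopumilus sp. rRNA",
                   "uncultured bacterium"),
    stringsAsFactors = FALSE)
  class(refs) <- c("ReferenceSet", "data.frame")
  refs
}

rc_oracle <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
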