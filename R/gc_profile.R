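## gc_profile: per-read GC content, dataset GC histograms, kernel-smoothed
## mode detection, and the low/high-GC read split.

#' GC content of nucleotide sequences
#'
#' `100 * (#G + #C) / (#A + #C + #G + #T)`; `N` bases are excluded from both
#' numerator and denominator. Case-insensitive.
#'
#' @param sequence Character vector of sequences (or a `ReadSet`).
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @export
gc_content <- function(sequence) {
  if (inherits(sequence, "ReadSet")) sequence <- sequence$sequences
  if (any(!nzchar(sequence))) stop("empty sequence")
  ss <- Biostrings::BStringSet(toupper(sequence))
  f <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0)) stop("sequence with zero non-N bases")
  unname(100 * (f[, "G"] + f[, "C"]) / denom)
}

#' GC histogram of a read set
#'
#' Bins are half-open `[lo, hi)` of width `bin_width` covering `[0, 100]`,
#' with the last bin closed so every read lands in exactly one bin.
#'
#' @param rs A `ReadSet` (non-empty).
#' @param bin_width Bin width in GC percentage points; must divide 100.
#' @return A `GCProfile`: list with `bin_edges` (length `nbins + 1`),
#'   `counts` (per-bin read counts) and `n_total`.
#' @export
gc_histogram <- function(rs, bin_width = 1) {
  stopifnot(inherits(rs, "ReadSet"))
  if (length(rs) == 0L) stop("empty ReadSet")
  if (bin_width <= 0 || abs(100 / bin_width - round(100 / bin_width)) > 1e-9) {
    stop("'bin_width' must divide 100")
  }
  gc <- gc_content(rs)
  edges <- seq(0, 100, by = bin_width)
  idx <- pmin(floor(gc / bin_width) + 1L, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, n_total = length(gc)),
            class = "GCProfile")
}

#' @export
print.GCProfile <- function(x, ...) {
  w <- diff(x$bin_edges[1:2])
  cat(sprintf("GCProfile: %d reads in %d bins of %g%%\n", x$n_total,
              length(x$counts), w))
  invisible(x)
}

## Gaussian-kernel smoothing of bin counts at the bin midpoints
smooth_profile <- function(profile, bandwidth) {
  mids <- profile$bin_edges[-length(profile$bin_edges)] +
    diff(profile$bin_edges) / 2
  sm <- vapply(mids, function(m) {
    w <- dnorm(mids - m, sd = bandwidth)
    sum(w * profile$counts) / sum(w)
  }, numeric(1L))
  list(mids = mids, smoothed = sm)
}

#' Detect modes of a GC profile
#'
#' The histogram is smoothed with a Gaussian kernel and local maxima with
#' prominence at least `min_prominence` times the global maximum are
#' reported, sorted by ascending mode position. The defaults resolve the
#' roughly 20-point separation between low- and high-GC freshwater
#' populations.
#'
#' @param p A `GCProfile`.
#' @param bandwidth Kernel standard deviation in GC percentage points.
#' @param min_prominence Minimum peak prominence as a fraction of the highest
#'   smoothed bin.
#' @return Data frame with columns `mode` (GC percent) and `height`
#'   (smoothed count); zero rows if no peak qualifies.
#' @export
detect_peaks <- function(p, bandwidth = 2, min_prominence = 0.05) {
  stopifnot(inherits(p, "GCProfile"))
  sp <- smooth_profile(p, bandwidth)
  s <- sp$smoothed
  n <- length(s)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) s[i] > s[i - 1L] else s[i] > 0
    right <- if (i < n) s[i] >= s[i + 1L] else s[i] > 0
    left && right
  }, logical(1L))
  peaks <- which(is_max)
  if (length(peaks) == 0L || max(s) <= 0) {
    return(data.frame(mode = numeric(0), height = numeric(0)))
  }
  prominence <- vapply(peaks, function(i) {
    h <- s[i]
    ## minimum on the walk towards the nearest higher bin (or the edge);
    ## an empty side leaves the base at h, zeroing boundary-bin prominence
    side_base <- function(idx) {
      lo <- h
      for (j in idx) {
        if (s[j] > h) return(lo)
        lo <- min(lo, s[j])
      }
      lo
    }
    left <- side_base(rev(seq_len(i - 1L)))
    right <- side_base(if (i < n) (i + 1L):n else integer(0))
    h - max(left, right)
  }, numeric(1L))
  keep <- prominence >= min_prominence * max(s)
  out <- data.frame(mode = sp$mids[peaks[keep]], height = s[peaks[keep]])
  out[order(out$mode), , drop = FALSE]
}

#' Split a read set at a GC threshold
#'
#' Reads with GC strictly below the threshold go to the low set, strictly
#' above to the high set; reads exactly at the threshold are assigned to the
#' low set so the split is a total partition.
#'
#' @param rs A `ReadSet`.
#' @param threshold GC percentage threshold, strictly between 0 and 100
#'   (default 50).
#' @return List with `low` and `high` `ReadSet`s whose sizes sum to the
#'   input size.
#' @export
split_by_gc <- function(rs, threshold = 50) {
  stopifnot(inherits(rs, "ReadSet"))
  if (threshold <= 0 || threshold >= 100) {
    stop("'threshold' must lie strictly between 0 and 100")
  }
  if (length(rs) == 0L) {
    return(list(low = rs, high = rs))
  }
  gc <- gc_content(rs)
  lo <- gc <= threshold
  list(low = read_set(rs$sequences[lo],
                      label = paste0(rs$label, "_lowGC"),
                      descriptions = rs$descriptions[lo]),
       high = read_set(rs$sequences[!lo],
                       label = paste0(rs$label, "_highGC"),
                       descriptions = rs$descriptions[!lo]))
}

#' Write a GC profile as two-column TSV
#'
#' Columns `bin_start` and `count`.
#'
#' @param p A `GCProfile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gc_profile <- function(p, path) {
  stopifnot(inherits(p, "GCProfile"))
  df <- data.frame(bin_start = p$bin_edges[-length(p$bin_edges)],
                   count = p$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
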