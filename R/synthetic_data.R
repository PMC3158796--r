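## synthetic_data: reference genomes, communities, paired communities with a
## controlled shared-genome fraction, marker-gene references, and functional
## profile pairs -- all with planted ground truth and seed-reproducible.

BASES <- c("A", "C", "G", "T")

## reverse complement of a character vector of sequences
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

## substitute exactly round(rate * len) positions with a different base
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n_mut <- round(rate * length(b))
  if (n_mut == 0L) return(seq)
  pos <- sample.int(length(b), n_mut)
  for (p in pos) {
    b[p] <- sample(setdiff(BASES, b[p]), 1L)
  }
  paste(b, collapse = "")
}

#' Simulate a reference genome with a target GC content
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc_target / 2` and
#' `P(A) = P(T) = (1 - gc_target) / 2`, so the realized GC fraction
#' concentrates around the target for long genomes.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_target Target GC fraction, strictly between 0 and 1.
#' @param seed Integer RNG seed; the same seed reproduces the same genome.
#' @param id Genome identifier.
#' @param taxon_label Taxon label carried into downstream binning truth
#'   (e.g. `"Actinobacteria-like"`).
#' @return A `SyntheticGenome`: list with `id`, `sequence`, `gc_target`,
#'   `taxon_label`.
#' @export
simulate_genome <- function(length, gc_target, seed, id = "genome",
                            taxon_label = "unknown") {
  if (length < 1000L) stop("'length' must be >= 1000")
  if (gc_target <= 0 || gc_target >= 1) {
    stop("'gc_target' must lie strictly between 0 and 1")
  }
  seq <- with_seed(seed, {
    p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
           (1 - gc_target) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(id = id, sequence = seq, gc_target = gc_target,
                 taxon_label = taxon_label),
            class = "SyntheticGenome")
}

#' Community ground truth
#'
#' Records, for a simulated read set, each read's source genome, start
#' coordinate and strand, together with the community's genome ids and
#' abundance vector and (for paired simulations) the planted fraction of
#' genomes shared with the partner community.
#'
#' @param genome_ids Character vector of genome ids in the community.
#' @param abundances Probability vector over `genome_ids` (sums to 1).
#' @param per_read_source Data frame with columns `read_id`, `genome_id`,
#'   `start`, `strand`, `taxon`.
#' @param shared_fraction Fraction of genomes shared with a paired community,
#'   or `NA` for unpaired simulations.
#' @return A `CommunityTruth`.
#' @export
community_truth <- function(genome_ids, abundances, per_read_source,
                            shared_fraction = NA_real_) {
  stopifnot(length(genome_ids) == length(abundances))
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  stopifnot(all(c("read_id", "genome_id", "start", "strand", "taxon") %in%
                  names(per_read_source)))
  structure(list(genome_ids = genome_ids, abundances = abundances,
                 per_read_source = per_read_source,
                 shared_fraction = shared_fraction),
            class = "CommunityTruth")
}

#' Simulate a shotgun read set from a multi-genome community
#'
#' Source genomes are drawn by abundance, strands uniformly, and read lengths
#' from a normal distribution (default mean 325 bp, the typical
#' pyrosequencing read length, sd 75) truncated to `[60, genome length]`.
#' Substitution errors are i.i.d. per base at `error_rate`; indels are not
#' modeled, so with `error_rate = 0` every read is an exact substring of its
#' source genome (or its reverse complement).
#'
#' @param genomes List of `SyntheticGenome` objects.
#' @param abundances Probability vector matching `genomes` (sums to 1).
#' @param n_reads Number of reads to draw (>= 1).
#' @param len_mean,len_sd Read-length distribution parameters in bp.
#' @param error_rate Per-base substitution probability, in `[0, 0.2]`.
#' @param seed Integer RNG seed.
#' @param label Dataset label for the resulting `ReadSet`.
#' @return List with elements `reads` (a `ReadSet`) and `truth`
#'   (a `CommunityTruth` with one row per read).
#' @export
simulate_community <- function(genomes, abundances, n_reads,
                               len_mean = 325, len_sd = 75,
                               error_rate = 0, seed = 1L,
                               label = "community") {
  if (n_reads < 1L) stop("'n_reads' must be >= 1")
  if (length(genomes) != length(abundances)) {
    stop("'abundances' must match 'genomes' in length")
  }
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  if (error_rate < 0 || error_rate > 0.2) {
    stop("'error_rate' must lie in [0, 0.2]")
  }
  gseqs <- vapply(genomes, `[[`, character(1L), "sequence")
  gids <- vapply(genomes, `[[`, character(1L), "id")
  gtax <- vapply(genomes, `[[`, character(1L), "taxon_label")
  glens <- nchar(gseqs)
  res <- with_seed(seed, {
    src <- sample.int(length(genomes), n_reads, replace = TRUE,
                      prob = abundances)
    lens <- integer(n_reads)
    todo <- seq_len(n_reads)
    while (length(todo) > 0L) { # rejection-sample the truncated normal
      draw <- round(rnorm(length(todo), len_mean, len_sd))
      ok <- draw >= 60 & draw <= glens[src[todo]]
      lens[todo[ok]] <- as.integer(draw[ok])
      todo <- todo[!ok]
    }
    starts <- vapply(seq_len(n_reads), function(i) {
      sample.int(glens[src[i]] - lens[i] + 1L, 1L)
    }, integer(1L))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(gseqs[src], starts, starts + lens - 1L)
    seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        b <- strsplit(s, "", fixed = TRUE)[[1L]]
        hit <- which(runif(length(b)) < error_rate)
        for (p in hit) b[p] <- sample(setdiff(BASES, b[p]), 1L)
        paste(b, collapse = "")
      }, character(1L), USE.NAMES = FALSE)
    }
    list(src = src, starts = starts, strands = strands, seqs = seqs)
  })
  ids <- sprintf("%s_r%05d", label, seq_len(n_reads))
  reads <- read_set(setNames(res$seqs, ids), label = label)
  truth <- community_truth(
    genome_ids = gids, abundances = abundances,
    per_read_source = data.frame(
      read_id = ids, genome_id = gids[res$src], start = res$starts,
      strand = res$strands, taxon = gtax[res$src],
      stringsAsFactors = FALSE))
  list(reads = reads, truth = truth)
}

#' Simulate two communities with a controlled shared-genome fraction
#'
#' Both communities hold `n_genomes` genomes; `round(shared_fraction *
#' n_genomes)` are drawn from a common pool and the rest are private to each
#' side. Genome GC targets alternate between the two `gc_modes` so that
#' pooled reads show the characteristic bimodal GC profile of low- and
#' high-GC freshwater populations. Genome-level abundances are uniform.
#'
#' @param shared_fraction Fraction of genomes common to both communities, in
#'   `[0, 1]`.
#' @param n_genomes Genomes per community (>= 2).
#' @param gc_modes Pair of GC fractions for the low- and high-GC genome
#'   classes (default `c(0.45, 0.65)`).
#' @param n_reads Reads per community.
#' @param seed Integer RNG seed.
#' @param genome_length Genome length in bp.
#' @param error_rate Per-base substitution rate for the reads.
#' @param labels Length-2 character vector of dataset labels.
#' @return List with `reads_a`, `reads_b` (`ReadSet`s) and `truth_a`,
#'   `truth_b` (`CommunityTruth`s recording `shared_fraction`).
#' @export
simulate_paired_communities <- function(shared_fraction, n_genomes,
                                        gc_modes = c(0.45, 0.65),
                                        n_reads = 500L, seed = 1L,
                                        genome_length = 20000L,
                                        error_rate = 0,
                                        labels = c("A", "B")) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("'shared_fraction' must lie in [0, 1]")
  }
  if (n_genomes < 2L) stop("'n_genomes' must be >= 2")
  n_shared <- round(shared_fraction * n_genomes)
  n_priv <- n_genomes - n_shared
  gc_for <- function(i) gc_modes[(i %% 2L) + 1L]
  mk <- function(id, i, sub_seed) {
    simulate_genome(genome_length, gc_for(i), seed = sub_seed, id = id,
                    taxon_label = sprintf("taxon_%s", id))
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_shared + 2L * n_priv + 2L))
  shared <- lapply(seq_len(n_shared), function(i) {
    mk(sprintf("shared_%02d", i), i, seeds[i])
  })
  priv_a <- lapply(seq_len(n_priv), function(i) {
    mk(sprintf("privA_%02d", i), i, seeds[n_shared + i])
  })
  priv_b <- lapply(seq_len(n_priv), function(i) {
    mk(sprintf("privB_%02d", i), i, seeds[n_shared + n_priv + i])
  })
  genomes_a <- c(shared, priv_a)
  genomes_b <- c(shared, priv_b)
  ab <- rep(1 / n_genomes, n_genomes)
  sim_a <- simulate_community(genomes_a, ab, n_reads, error_rate = error_rate,
                              seed = seeds[n_shared + 2L * n_priv + 1L],
                              label = labels[1L])
  sim_b <- simulate_community(genomes_b, ab, n_reads, error_rate = error_rate,
                              seed = seeds[n_shared + 2L * n_priv + 2L],
                              label = labels[2L])
  sim_a$truth$shared_fraction <- shared_fraction
  sim_b$truth$shared_fraction <- shared_fraction
  list(reads_a = sim_a$reads, reads_b = sim_b$reads,
       truth_a = sim_a$truth, truth_b = sim_b$truth,
       genomes_a = genomes_a, genomes_b = genomes_b)
}

#' Build a marker-gene reference collection with named and uncultured entries
#'
#' Emulates an rRNA reference database: `n_named` entries carry genus and
#' higher-rank labels, `n_uncultured` entries are annotated only as
#' "uncultured bacterium". All entries are copies of per-taxon seed markers
#' mutated at the stated divergence, so identity-threshold classification has
#' a known answer.
#'
#' @param n_named,n_uncultured Numbers of named / uncultured entries
#'   (`n_named + n_uncultured >= 1`).
#' @param divergence Per-entry substitution fraction relative to its seed
#'   marker, at most 0.5.
#' @param seed Integer RNG seed.
#' @param marker_length Marker length in bp (default 1200, a near-full-length
#'   small-subunit rRNA gene).
#' @return A `ReferenceSet`: data frame with columns `id`, `sequence`,
#'   `genus`, `higher_taxon`, `annotation`.
#' @export
build_marker_reference <- function(n_named, n_uncultured, divergence = 0.1,
                                   seed = 1L, marker_length = 1200L) {
  if (n_named + n_uncultured < 1L) stop("at least one entry is required")
  if (divergence > 0.5) stop("'divergence' must be <= 0.5")
  higher <- c("Actinobacteria", "Betaproteobacteria", "Alphaproteobacteria",
              "Gammaproteobacteria", "Crenarchaeota")
  with_seed(seed, {
    base_marker <- paste(sample(BASES, marker_length, replace = TRUE),
                         collapse = "")
    n <- n_named + n_uncultured
    rows <- lapply(seq_len(n), function(i) {
      named <- i <= n_named
      ht <- higher[((i - 1L) %% length(higher)) + 1L]
      data.frame(
        id = sprintf("ref_%03d", i),
        sequence = mutate_sequence(base_marker, divergence),
        genus = if (named) sprintf("Genus%03d", i) else NA_character_,
        higher_taxon = if (named) ht else "Bacteria",
        annotation = if (named) {
          sprintf("Genus%03d sp. small-subunit rRNA gene", i)
        } else "uncultured bacterium",
        stringsAsFactors = FALSE)
    })
    refs <- do.call(rbind, rows)
    class(refs) <- c("ReferenceSet", "data.frame")
    refs
  })
}

#' Simulate a pair of functional category-count profiles with planted effects
#'
#' Counts are multinomial draws over a shared category universe. Dataset A
#' uses the baseline proportions; dataset B uses the baseline with the
#' planted categories' proportions multiplied by their fold change and the
#' vector renormalized. The returned truth lists the planted categories.
#'
#' @param n_categories Number of categories.
#' @param totals Length-2 integer vector of total counts, each >= 1000.
#' @param planted Named numeric vector of fold changes (> 0); names must be
#'   category names of the form `C###`. Empty by default (null profile pair).
#' @param planted_baseline Optional numeric vector (same length as `planted`)
#'   of baseline proportions for the planted categories; remaining mass is
#'   spread uniformly over the other categories.
#' @param seed Integer RNG seed.
#' @return List with `a`, `b` (two [category_counts()] tables) and `truth`
#'   (character vector of planted category names).
#' @export
simulate_profile_pair <- function(n_categories, totals = c(10000L, 10000L),
                                  planted = numeric(0),
                                  planted_baseline = NULL, seed = 1L) {
  if (any(totals < 1000L)) stop("'totals' must each be >= 1000")
  if (any(planted <= 0)) stop("planted fold changes must be > 0")
  cats <- sprintf("C%03d", seq_len(n_categories))
  if (length(planted) > 0L && !all(names(planted) %in% cats)) {
    stop("planted category not among the ", n_categories, " categories")
  }
  baseline <- rep(1 / n_categories, n_categories)
  names(baseline) <- cats
  if (!is.null(planted_baseline)) {
    stopifnot(length(planted_baseline) == length(planted))
    baseline[names(planted)] <- planted_baseline
    others <- setdiff(cats, names(planted))
    baseline[others] <- (1 - sum(planted_baseline)) / length(others)
  }
  p_a <- baseline / sum(baseline)
  p_b <- baseline
  p_b[names(planted)] <- p_b[names(planted)] * planted
  p_b <- p_b / sum(p_b)
  counts <- with_seed(seed, {
    list(a = rmultinom(1L, totals[1L], p_a)[, 1L],
         b = rmultinom(1L, totals[2L], p_b)[, 1L])
  })
  list(a = category_counts(setNames(counts$a, cats), label = "A"),
       b = category_counts(setNames(counts$b, cats), label = "B"),
       truth = names(planted))
}

#' Write synthetic genomes as FASTA
#'
#' @param genomes List of `SyntheticGenome` objects.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_genomes_fasta <- function(genomes, path) {
  seqs <- setNames(vapply(genomes, `[[`, character(1L), "sequence"),
                   vapply(genomes, `[[`, character(1L), "id"))
  write_fasta(read_set(seqs, label = "genomes"), path)
}
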