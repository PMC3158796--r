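## pipeline: orchestration of the full comparative analysis on synthetic
## communities, with a flat key:value config, per-stage artifacts in standard
## text formats, and a manifest. Fulfils the role of a command-line driver
## through plain R functions; every stage is also callable standalone.

#' Default pipeline configuration
#'
#' Flat list of every stage parameter with its standard default: alignment
#' scoring, the >70%/>100 bp distance hit filter, the 95%/50 bp recruitment
#' criteria, the >90%/50% coverage overlap criterion, the rRNA identity
#' thresholds (95/90, >100 bp), the 1e-5/50 bp binning cutoffs, and the
#' q 0.05 / 100 sequences / 2-fold enrichment filter. Simulation settings
#' default to three communities of 2000 reads, 325 +/- 75 bp, drawn from
#' 20 kb genomes at the 45%/65% GC modes.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param ... Overrides for individual keys, e.g. `n_reads = 500`.
#' @return A named list of class `RunConfig`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # simulation
    n_datasets = 3L, n_genomes = 6L, genome_length = 20000L,
    shared_fraction = 0.5, n_reads = 2000L, len_mean = 325, len_sd = 75,
    error_rate = 0.01, gc_low = 0.45, gc_high = 0.65,
    # alignment
    seed_k = 11L, match = 1L, mismatch = -2L, xdrop = 20,
    lambda = 1.28, K = 0.46, max_evalue = 10,
    # distance
    dist_min_identity = 70, dist_min_len = 100, dist_policy = "best-per-query",
    dist_form = "jaccard",
    # gc
    gc_bin_width = 1, gc_bandwidth = 2, gc_min_prominence = 0.05,
    gc_split_threshold = 50,
    # recruitment
    recruit_min_identity = 95, recruit_min_len = 50,
    overlap_min_identity = 90, overlap_min_query_cov = 0.5,
    # rRNA classification
    rrna_min_len = 100, rrna_genus_identity = 95, rrna_unidentified_below = 90,
    rrna_n_named = 8L, rrna_n_uncultured = 4L, rrna_divergence = 0.08,
    # binning
    bin_max_evalue = 1e-5, bin_min_len = 50,
    # enrichment
    enrich_n_categories = 50L, enrich_total = 10000L,
    enrich_q_max = 0.05, enrich_min_seqs = 100, enrich_min_ratio = 2,
    enrich_planted_fold = 3, enrich_planted_baseline = 0.01
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) stop("unknown config key: ", unknown[1L])
  cfg[names(dots)] <- dots
  class(cfg) <- "RunConfig"
  cfg
}

#' Write / read a pipeline configuration
#'
#' Flat key: value text (YAML); round-trips losslessly through
#' [read_config()].
#'
#' @param cfg A `RunConfig`.
#' @param path File path.
#' @return Invisibly `path` (write) or a `RunConfig` (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) stop("unknown config key: ", unknown[1L])
  base[names(cfg)] <- cfg
  base$seed <- as.integer(base$seed)
  class(base) <- "RunConfig"
  base
}

pipeline_params <- function(cfg) {
  alignment_params(k = cfg$seed_k, match = cfg$match, mismatch = cfg$mismatch,
                   xdrop = cfg$xdrop, lambda = cfg$lambda, K = cfg$K,
                   max_evalue = cfg$max_evalue)
}

#' Run the full comparative pipeline on synthetic communities
#'
#' Executes simulate, align, distance/tree, GC, recruitment, classification
#' (rRNA rules plus bulk best-hit binning) and enrichment, writing every
#' intermediate as TSV/FASTA/Newick under `out_dir` plus a `manifest.tsv`
#' listing each stage's outputs, parameters and elapsed time. The same seed
#' and config give byte-identical text outputs.
#'
#' Dataset 1 and 2 share `shared_fraction` of their genomes; every further
#' dataset is simulated from its own private genome pool, providing a
#' distant comparison point for the tree.
#'
#' @param cfg A `RunConfig` from [default_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages (default `FALSE`); messages go to
#'   standard error.
#' @return Invisibly, a list with the in-memory stage results (`datasets`,
#'   `dm`, `tree`, `gc`, `recruitment`, `rrna`, `binning`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("run_"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- pipeline_params(cfg)
  manifest <- list()
  note <- function(...) if (!quiet) message(...)
  stage <- function(name, inputs, outputs, parameters, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name, inputs = inputs, outputs = outputs,
      parameters = parameters,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      stringsAsFactors = FALSE)
    note(sprintf("[%s] done", name))
    res
  }
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 16L))

  ## 1. simulate communities ------------------------------------------------
  sim <- stage("simulate", "config", "reads_*.fasta,genomes_*.fasta,truth_*.tsv",
               sprintf("n_datasets=%d n_reads=%d shared_fraction=%g",
                       cfg$n_datasets, cfg$n_reads, cfg$shared_fraction), {
    pair <- simulate_paired_communities(
      cfg$shared_fraction, cfg$n_genomes, c(cfg$gc_low, cfg$gc_high),
      n_reads = cfg$n_reads, seed = seeds[1L],
      genome_length = cfg$genome_length, error_rate = cfg$error_rate,
      labels = c("D1", "D2"))
    datasets <- list(pair$reads_a, pair$reads_b)
    truths <- list(pair$truth_a, pair$truth_b)
    genomes <- list(pair$genomes_a, pair$genomes_b)
    if (cfg$n_datasets > 2L) {
      for (i in 3:cfg$n_datasets) {
        gseeds <- with_seed(seeds[i],
                            sample.int(.Machine$integer.max - 1L,
                                       cfg$n_genomes + 1L))
        gset <- lapply(seq_len(cfg$n_genomes), function(g) {
          gc <- if (g %% 2L == 1L) cfg$gc_low else cfg$gc_high
          simulate_genome(cfg$genome_length, gc, seed = gseeds[g],
                          id = sprintf("privD%d_%02d", i, g),
                          taxon_label = sprintf("taxon_privD%d_%02d", i, g))
        })
        extra <- simulate_community(gset, rep(1 / cfg$n_genomes,
                                              cfg$n_genomes),
                                    cfg$n_reads, len_mean = cfg$len_mean,
                                    len_sd = cfg$len_sd,
                                    error_rate = cfg$error_rate,
                                    seed = gseeds[cfg$n_genomes + 1L],
                                    label = sprintf("D%d", i))
        datasets[[i]] <- extra$reads
        truths[[i]] <- extra$truth
        genomes[[i]] <- gset
      }
    }
    for (i in seq_along(datasets)) {
      datasets[[i]] <- filter_min_length(datasets[[i]])
      write_fasta(datasets[[i]], file.path(out_dir,
                                           sprintf("reads_D%d.fasta", i)))
      write_genomes_fasta(genomes[[i]],
                          file.path(out_dir, sprintf("genomes_D%d.fasta", i)))
      write.table(truths[[i]]$per_read_source,
                  file.path(out_dir, sprintf("truth_D%d.tsv", i)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(datasets = datasets, truths = truths, genomes = genomes)
  })

  ## 2. all-vs-all alignment ------------------------------------------------
  hits <- stage("align", "reads_*.fasta", "hits_*.tsv",
                sprintf("k=%d match=%d mismatch=%d", cfg$seed_k, cfg$match,
                        cfg$mismatch), {
    n <- length(sim$datasets)
    hl <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        ht <- find_hits(sim$datasets[[i]], sim$datasets[[j]], params)
        write_tabular_hits(ht, file.path(out_dir,
                                         sprintf("hits_D%d_vs_D%d.tsv", i, j)))
        hl[[sprintf("%d_%d", i, j)]] <- ht
      }
    }
    hl
  })

  ## 3. distance matrix and tree -------------------------------------------
  dm <- stage("distance", "hits_*.tsv", "distance_matrix.tsv,tree.nwk",
              sprintf("min_identity=%g min_len=%g policy=%s form=%s",
                      cfg$dist_min_identity, cfg$dist_min_len,
                      cfg$dist_policy, cfg$dist_form), {
    n <- length(sim$datasets)
    labels <- vapply(sim$datasets, function(d) d$label, character(1L))
    score_of <- function(ht) {
      total_bit_score(filter_distance_hits(ht, cfg$dist_min_identity,
                                           cfg$dist_min_len),
                      cfg$dist_policy)
    }
    selfs <- vapply(seq_len(n), function(i) {
      score_of(hits[[sprintf("%d_%d", i, i)]])
    }, numeric(1L))
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        cross <- (score_of(hits[[sprintf("%d_%d", i, j)]]) +
                    score_of(hits[[sprintf("%d_%d", j, i)]])) / 2
        cross <- min(cross, selfs[i], selfs[j])
        m[i, j] <- m[j, i] <- jaccard_distance(cross, selfs[i], selfs[j],
                                               form = cfg$dist_form)
      }
    }
    dmat <- structure(m, class = c("DistanceMatrix", class(m)))
    write_distance_matrix(dmat, file.path(out_dir, "distance_matrix.tsv"))
    tree <- if (n >= 3L) {
      tr <- neighbor_joining(dmat)
      write_newick(tr, file.path(out_dir, "tree.nwk"))
      tr
    } else NULL
    list(dm = dmat, tree = tree)
  })

  ## 4. GC profiles ---------------------------------------------------------
  gc <- stage("gc", "reads_*.fasta", "gc_profile_*.tsv,gc_peaks.tsv",
              sprintf("bin_width=%g bandwidth=%g", cfg$gc_bin_width,
                      cfg$gc_bandwidth), {
    out <- lapply(seq_along(sim$datasets), function(i) {
      p <- gc_histogram(sim$datasets[[i]], cfg$gc_bin_width)
      write_gc_profile(p, file.path(out_dir,
                                    sprintf("gc_profile_D%d.tsv", i)))
      pk <- detect_peaks(p, cfg$gc_bandwidth, cfg$gc_min_prominence)
      split <- split_by_gc(sim$datasets[[i]], cfg$gc_split_threshold)
      list(profile = p, peaks = pk,
           n_low = length(split$low), n_high = length(split$high))
    })
    peaks <- do.call(rbind, lapply(seq_along(out), function(i) {
      pk <- out[[i]]$peaks
      if (nrow(pk) == 0L) return(NULL)
      data.frame(dataset = sim$datasets[[i]]$label, pk,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(peaks)) {
      peaks <- data.frame(dataset = character(0), mode = numeric(0),
                          height = numeric(0))
    }
    peaks$height <- round(peaks$height, 6)
    write.table(peaks, file.path(out_dir, "gc_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out
  })

  ## 5. recruitment against dataset-1 genomes -------------------------------
  recr <- stage("recruit", "reads_D1.fasta,genomes_D1.fasta",
                "recruitment_*.tsv,genome_ranking.tsv,overlap.tsv",
                sprintf("min_identity=%g min_len=%g", cfg$recruit_min_identity,
                        cfg$recruit_min_len), {
    genomes <- sim$genomes[[1L]]
    gseqs <- setNames(vapply(genomes, `[[`, character(1L), "sequence"),
                      vapply(genomes, `[[`, character(1L), "id"))
    ht_all <- find_hits(sim$datasets[[1L]], gseqs, params)
    results <- lapply(names(gseqs), function(gid) {
      ht_g <- hit_table(as.data.frame(ht_all)[ht_all$sseqid == gid, ,
                                              drop = FALSE],
                        attr(ht_all, "query_label"), gid)
      r <- recruit(ht_g, nchar(gseqs[[gid]]), cfg$recruit_min_identity,
                   cfg$recruit_min_len, genome_id = gid)
      write_recruitment(r, file.path(out_dir,
                                     sprintf("recruitment_%s.tsv", gid)))
      r
    })
    ranking <- rank_genomes(results)
    write.table(ranking, file.path(out_dir, "genome_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ht12 <- hits[["1_2"]]
    ov <- overlap_fraction(sim$datasets[[1L]], ht12,
                           cfg$overlap_min_identity, cfg$overlap_min_query_cov)
    write.table(data.frame(query = "D1", subject = "D2",
                           overlap_fraction = round(ov, 6)),
                file.path(out_dir, "overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(results = results, ranking = ranking, overlap = ov)
  })

  ## 6. classification: rRNA rules + bulk binning ---------------------------
  cls <- stage("classify", "reads_*.fasta", "rrna_*.tsv,binning_*.tsv",
               sprintf("rrna>%g/%g/%gbp bin<=%g/%gbp", cfg$rrna_genus_identity,
                       cfg$rrna_unidentified_below, cfg$rrna_min_len,
                       cfg$bin_max_evalue, cfg$bin_min_len), {
    refs <- build_marker_reference(cfg$rrna_n_named, cfg$rrna_n_uncultured,
                                   cfg$rrna_divergence, seed = seeds[8L])
    write_reference_fasta(refs, file.path(out_dir, "marker_refs.fasta"))
    ## rRNA-like query fragments: reads drawn from the named markers
    marker_genomes <- lapply(seq_len(min(4L, cfg$rrna_n_named)), function(i) {
      structure(list(id = refs$id[i],
                     sequence = paste(rep(refs$sequence[i], 10L),
                                      collapse = ""),
                     gc_target = 0.5,
                     taxon_label = refs$higher_taxon[i]),
                class = "SyntheticGenome")
    })
    nm <- length(marker_genomes)
    rr <- simulate_community(marker_genomes, rep(1 / nm, nm), 200L,
                             error_rate = 0.02, seed = seeds[9L],
                             label = "rrna")
    ht_rrna <- find_hits(rr$reads, setNames(refs$sequence, refs$id), params)
    assign_rrna <- classify_rrna(ht_rrna, refs, read_ids = read_ids(rr$reads),
                                 min_len = cfg$rrna_min_len,
                                 genus_identity = cfg$rrna_genus_identity,
                                 unidentified_below = cfg$rrna_unidentified_below)
    write.table(as.data.frame(assign_rrna),
                file.path(out_dir, "rrna_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prof_rrna <- taxon_profile(assign_rrna)
    write.table(as.data.frame(prof_rrna),
                file.path(out_dir, "rrna_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ## bulk binning of dataset 1 against its own genome pool
    genomes <- sim$genomes[[1L]]
    gseqs <- setNames(vapply(genomes, `[[`, character(1L), "sequence"),
                      vapply(genomes, `[[`, character(1L), "id"))
    gtaxa <- setNames(vapply(genomes, `[[`, character(1L), "taxon_label"),
                      vapply(genomes, `[[`, character(1L), "id"))
    ht_bin <- find_hits(sim$datasets[[1L]], gseqs, params)
    assign_bin <- bin_reads_best_hit(ht_bin, gtaxa,
                                     read_ids = read_ids(sim$datasets[[1L]]),
                                     max_evalue = cfg$bin_max_evalue,
                                     min_len = cfg$bin_min_len)
    write.table(as.data.frame(assign_bin),
                file.path(out_dir, "binning_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prof_bin <- taxon_profile(assign_bin)
    prof_out <- as.data.frame(prof_bin)
    prof_out$percent_classified <- round(prof_out$percent_classified, 6)
    prof_out$percent_total <- round(prof_out$percent_total, 6)
    write.table(prof_out, file.path(out_dir, "binning_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(refs = refs, rrna = assign_rrna, rrna_profile = prof_rrna,
         binning = assign_bin, binning_profile = prof_bin)
  })

  ## 7. functional enrichment ------------------------------------------------
  enr <- stage("enrich", "config", "profile_A.tsv,profile_B.tsv,enrichment.tsv",
               sprintf("q<=%g min_seqs=%g ratio>%g", cfg$enrich_q_max,
                       cfg$enrich_min_seqs, cfg$enrich_min_ratio), {
    planted <- setNames(cfg$enrich_planted_fold, "C001")
    pp <- simulate_profile_pair(cfg$enrich_n_categories,
                                c(cfg$enrich_total, cfg$enrich_total),
                                planted = planted,
                                planted_baseline = cfg$enrich_planted_baseline,
                                seed = seeds[10L])
    write_category_counts(pp$a, file.path(out_dir, "profile_A.tsv"))
    write_category_counts(pp$b, file.path(out_dir, "profile_B.tsv"))
    et <- compare_profiles(pp$a, pp$b, cfg$enrich_q_max, cfg$enrich_min_seqs,
                           cfg$enrich_min_ratio)
    write_enrichment(et, file.path(out_dir, "enrichment.tsv"))
    dr <- domain_abundance_ratio(pp$a, pp$b)
    dr$ratio <- round(dr$ratio, 6)
    write.table(dr, file.path(out_dir, "domain_ratio.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(profiles = pp, enrichment = et, domain_ratio = dr)
  })

  manifest_df <- do.call(rbind, manifest)
  write.table(manifest_df, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(out_dir = out_dir, datasets = sim$datasets,
                 truths = sim$truths, dm = dm$dm, tree = dm$tree, gc = gc,
                 recruitment = recr, rrna = cls$rrna, binning = cls$binning,
                 enrichment = enr$enrichment, manifest = manifest_df))
}
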