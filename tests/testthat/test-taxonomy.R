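test_that("the five rRNA rule cases are each handled", {
  refs <- ref_fixture()

  genus_hit <- make_hits("r1", "ref_named1", pident = 96.2, length = 140)
  a <- classify_rrna(genus_hit, refs)
  expect_identical(a$rank, "genus")
  expect_identical(a$taxon, "Polynucleobacter")

  higher_hit <- make_hits("r2", "ref_named2", pident = 92, length = 200)
  b <- classify_rrna(higher_hit, refs)
  expect_identical(b$rank, "higher")
  expect_identical(b$taxon, "Crenarchaeota")

  low_hit <- make_hits("r3", "ref_named1", pident = 89, length = 200)
  expect_identical(classify_rrna(low_hit, refs)$rank, "unidentified")

  unc_only <- make_hits("r4", "ref_unc", pident = 99, length = 300)
  d <- classify_rrna(unc_only, refs)
  expect_identical(d$rank, "unidentified")
  expect_match(d$note, "uncultured")

  short <- make_hits("r5", "ref_named1", pident = 99, length = 95)
  expect_identical(classify_rrna(short, refs)$rank, "unidentified")
})

test_that("rRNA boundary identities 95 and 90 fall in the higher-taxon band", {
  refs <- ref_fixture()
  at95 <- classify_rrna(make_hits("r", "ref_named1", pident = 95,
                                  length = 150), refs)
  expect_identical(at95$rank, "higher")
  at90 <- classify_rrna(make_hits("r", "ref_named1", pident = 90,
                                  length = 150), refs)
  expect_identical(at90$rank, "higher")
})

test_that("the rRNA rule engine is total and exhaustive over identities", {
  refs <- ref_fixture()
  set.seed(51)
  for (rep in 1:50) {
    pid <- round(runif(1, 50, 100), 2)
    a <- classify_rrna(make_hits("r", "ref_named1", pident = pid,
                                 length = 150), refs)
    expect_identical(nrow(a), 1L)
    expected <- if (pid > 95) "genus" else if (pid >= 90) "higher" else
      "unidentified"
    expect_identical(a$rank, expected)
  }
  # reads without hits are still assigned
  none <- classify_rrna(make_hits("r1", "ref_named1", pident = 99,
                                  length = 150), refs,
                        read_ids = c("r1", "r_nohit"))
  expect_identical(nrow(none), 2L)
  expect_identical(none$rank[none$read_id == "r_nohit"], "unidentified")
})

test_that("the named best hit wins over a higher-identity uncultured hit", {
  refs <- ref_fixture()
  ht <- make_hits(c("r", "r"), c("ref_unc", "ref_named1"),
                  pident = c(99.9, 96.5), length = c(300, 200),
                  bitscore = c(500, 300))
  a <- classify_rrna(ht, refs)
  expect_identical(a$rank, "genus")
  expect_identical(a$taxon, "Polynucleobacter")
})

test_that("classification errors on reference ids missing from the collection", {
  refs <- ref_fixture()
  expect_error(classify_rrna(make_hits("r", "ghost", pident = 99,
                                       length = 150), refs), "missing")
})

test_that("best-hit binning applies e-value and length cutoffs", {
  taxa <- c(gA = "Actinobacteria", gB = "Betaproteobacteria")
  ht <- make_hits(c("r1", "r2", "r3"), c("gA", "gA", "gB"),
                  pident = 98, length = c(80, 40, 80),
                  evalue = c(1e-10, 1e-10, 1e-3), bitscore = 100)
  a <- bin_reads_best_hit(ht, taxa)
  expect_identical(a$taxon[a$read_id == "r1"], "Actinobacteria")
  expect_identical(a$taxon[a$read_id == "r2"], "unclassified") # too short
  expect_identical(a$taxon[a$read_id == "r3"], "unclassified") # evalue fail
  expect_error(bin_reads_best_hit(ht, c(gA = "x")), "taxon mapping")

  # bit-score ties break by ascending subject id
  tie <- make_hits(c("r", "r"), c("gB", "gA"), pident = 98, length = 80,
                   evalue = 1e-10, bitscore = 100)
  expect_identical(bin_reads_best_hit(tie, taxa)$taxon, "Actinobacteria")
})

test_that("best-hit binning agrees with a brute-force scan on random tables", {
  taxa <- setNames(paste0("taxon_", sprintf("s%02d", 1:4)),
                   sprintf("s%02d", 1:4))
  for (seed in 1:5) {
    ht <- random_hits(100, n_queries = 25, seed = seed)
    a <- bin_reads_best_hit(ht, taxa)
    df <- as.data.frame(ht)
    for (rid in unique(df$qseqid)) {
      h <- df[df$qseqid == rid & df$evalue <= 1e-5 & df$length >= 50, ]
      want <- if (nrow(h) == 0) "unclassified" else {
        h <- h[order(-h$bitscore, h$sseqid), ]
        taxa[[h$sseqid[1]]]
      }
      expect_identical(a$taxon[a$read_id == rid], unname(want))
    }
  }
})

test_that("binned reads match their true source taxon on a 3-taxon community", {
  genomes <- lapply(1:3, function(i) {
    simulate_genome(12000, 0.5, seed = 52 + i, id = sprintf("g%d", i),
                    taxon_label = sprintf("taxon%d", i))
  })
  sim <- simulate_community(genomes, c(1, 1, 1) / 3, 600, error_rate = 0.01,
                            seed = 56)
  gseqs <- setNames(vapply(genomes, `[[`, character(1), "sequence"),
                    vapply(genomes, `[[`, character(1), "id"))
  gtaxa <- setNames(vapply(genomes, `[[`, character(1), "taxon_label"),
                    vapply(genomes, `[[`, character(1), "id"))
  ht <- find_hits(sim$reads, gseqs)
  a <- bin_reads_best_hit(ht, gtaxa, read_ids = read_ids(sim$reads))
  merged <- merge(as.data.frame(a), sim$truth$per_read_source, by = "read_id")
  cls <- merged[merged$rank != "unidentified", ]
  expect_gt(nrow(cls) / nrow(merged), 0.9)
  expect_gte(mean(cls$taxon.x == cls$taxon.y), 0.95)
})

test_that("taxon profiles conserve counts and percentages", {
  a <- taxon_assignment <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    taxon = c(rep("Actinobacteria", 30), rep("Betaproteobacteria", 20),
              rep("unclassified", 50)),
    rank = c(rep("higher", 50), rep("unidentified", 50)),
    best_identity = 95, note = "", stringsAsFactors = FALSE)
  class(a) <- c("TaxonAssignment", "data.frame")
  p <- taxon_profile(a)
  expect_identical(p$taxon[nrow(p)], "unclassified")
  expect_equal(p$percent_total[p$taxon == "unclassified"], 50)
  expect_equal(sum(p$percent_total), 100)
  expect_equal(sum(p$percent_classified, na.rm = TRUE), 100)
  expect_identical(sum(p$count), 100L)
  # counts ordered descending among classified taxa
  expect_identical(p$taxon[1], "Actinobacteria")

  empty <- a[0, ]
  class(empty) <- c("TaxonAssignment", "data.frame")
  pe <- taxon_profile(empty)
  expect_identical(pe$count, 0L)
})

test_that("reference FASTA with structured headers round-trips", {
  refs <- build_marker_reference(3, 2, divergence = 0.05, seed = 57)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(refs, f)
  back <- read_reference_fasta(f)
  expect_identical(back$id, refs$id)
  expect_identical(back$sequence, refs$sequence)
  expect_identical(back$genus, refs$genus)
  expect_identical(back$annotation, refs$annotation)
})

test_that("simulated rRNA fragments from a named marker recover its genus", {
  refs <- build_marker_reference(5, 2, divergence = 0.1, seed = 58)
  target <- refs[1, ]
  # fragments of the named marker mutated at 4%: above the 95% genus bar
  frag_genome <- structure(list(id = "m", sequence = paste(
    rep(target$sequence, 5), collapse = ""), gc_target = 0.5,
    taxon_label = target$higher_taxon), class = "SyntheticGenome")
  sim <- simulate_community(list(frag_genome), 1, 50, error_rate = 0.01,
                            seed = 59, len_mean = 250, len_sd = 30)
  ht <- find_hits(sim$reads, setNames(refs$sequence, refs$id))
  a <- classify_rrna(ht, refs, read_ids = read_ids(sim$reads))
  genus_calls <- a$taxon[a$rank == "genus"]
  expect_gt(length(genus_calls) / nrow(a), 0.9)
  expect_true(all(genus_calls == target$genus))
})
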