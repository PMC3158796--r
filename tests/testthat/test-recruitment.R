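test_that("recruitment applies inclusive 95%/50 bp thresholds, best hit per read", {
  ht <- make_hits(qseqid = c("q1", "q2", "q3", "q4"),
                  pident = c(94.9, 96, 99, 95),
                  length = c(100, 60, 45, 50),
                  sstart = c(10, 100, 200, 300))
  r <- recruit(ht, genome_length = 5000)
  # 94.9% excluded (below inclusive minimum), 45 bp excluded
  expect_identical(r$n_recruited, 2L)
  expect_setequal(r$points$read_id, c("q2", "q4"))

  # best hit per read only
  dup <- make_hits(qseqid = c("q1", "q1"), pident = c(96, 99),
                   length = c(60, 80), bitscore = c(50, 90),
                   sstart = c(1, 1001))
  r2 <- recruit(dup, genome_length = 5000)
  expect_identical(r2$n_recruited, 1L)
  expect_identical(r2$points$position, 1001L + 39L) # midpoint of best hit

  expect_error(recruit(ht, genome_length = 100), "genome_length")
})

test_that("recruitment equals a brute-force filter on random hit tables", {
  for (seed in 1:5) {
    ht <- random_hits(120, n_queries = 40, seed = seed)
    r <- recruit(ht, genome_length = 10000)
    df <- as.data.frame(ht)
    pass <- df[df$pident >= 95 & df$length >= 50, ]
    expect_identical(r$n_recruited, length(unique(pass$qseqid)))
    expect_setequal(r$points$read_id, unique(pass$qseqid))
    expect_true(all(r$points$identity >= 95))
  }
})

test_that("error-free reads from a genome are all recruited at identity 100", {
  g <- simulate_genome(15000, 0.5, seed = 41, id = "g")
  sim <- simulate_community(list(g), 1, 150, error_rate = 0, seed = 42)
  ht <- find_hits(sim$reads, c(g = g$sequence))
  r <- recruit(ht, genome_length = 15000)
  expect_identical(r$n_recruited, 150L)
  expect_true(all(r$points$identity == 100))
})

test_that("genome ranking sorts by count with id tie-breaks", {
  mk <- function(id, n) {
    structure(list(genome_id = id,
                   points = data.frame(position = seq_len(n),
                                       identity = rep(99, n),
                                       read_id = sprintf("%s_%d", id,
                                                         seq_len(n))),
                   n_recruited = n, genome_length = 1000L),
              class = "RecruitmentResult")
  }
  rk <- rank_genomes(list(mk("g1", 10), mk("g2", 30), mk("g3", 20)))
  expect_identical(rk$genome_id, c("g2", "g3", "g1"))
  tie <- rank_genomes(list(mk("gb", 5), mk("ga", 5)))
  expect_identical(tie$genome_id, c("ga", "gb"))
  expect_identical(nrow(rank_genomes(list(mk("solo", 3)))), 1L)
  expect_error(rank_genomes(list()), "at least one")
})

test_that("recruitment ranking recovers planted community abundances", {
  genomes <- lapply(1:3, function(i) {
    simulate_genome(15000, c(0.45, 0.55, 0.65)[i], seed = 42 + i,
                    id = sprintf("g%d", i))
  })
  sim <- simulate_community(genomes, c(0.6, 0.3, 0.1), 1500,
                            error_rate = 0.02, seed = 46)
  gseqs <- setNames(vapply(genomes, `[[`, character(1), "sequence"),
                    vapply(genomes, `[[`, character(1), "id"))
  ht <- find_hits(sim$reads, gseqs)
  results <- lapply(names(gseqs), function(gid) {
    sub <- hit_table(as.data.frame(ht)[ht$sseqid == gid, , drop = FALSE],
                     "reads", gid)
    recruit(sub, nchar(gseqs[[gid]]), genome_id = gid)
  })
  rk <- rank_genomes(results)
  expect_identical(rk$genome_id, c("g1", "g2", "g3"))
})

test_that("overlap fraction counts qualifying reads with coverage and identity", {
  reads <- read_set(setNames(vapply(1:10, function(i) random_seq(100, 50 + i),
                                    character(1)), paste0("q", 1:10)))
  # 6 reads with full-coverage 95% hits, 4 with low identity
  ht <- make_hits(qseqid = paste0("q", 1:10),
                  pident = c(rep(95, 6), rep(85, 4)),
                  length = 100, qstart = 1, qend = 100)
  expect_equal(overlap_fraction(reads, ht), 0.6)
  expect_equal(overlap_fraction(reads, hit_table()), 0)

  # half-coverage boundary is inclusive
  half <- make_hits(qseqid = "q1", pident = 95, length = 50, qstart = 1,
                    qend = 50)
  expect_equal(overlap_fraction(reads, half), 0.1)
  # identity boundary is strict (>90)
  at90 <- make_hits(qseqid = "q1", pident = 90, length = 100, qstart = 1,
                    qend = 100)
  expect_equal(overlap_fraction(reads, at90), 0)

  bad <- make_hits(qseqid = "nope", pident = 95, length = 100)
  expect_error(overlap_fraction(reads, bad), "absent")
})

test_that("overlap fraction of a dataset against itself is 1", {
  g <- simulate_genome(10000, 0.5, seed = 47)
  sim <- simulate_community(list(g), 1, 60, error_rate = 0, seed = 48)
  ht <- find_hits(sim$reads, sim$reads)
  expect_equal(overlap_fraction(sim$reads, ht), 1)
})

test_that("overlap fraction is monotone as thresholds relax", {
  for (seed in 1:3) {
    ht <- random_hits(100, n_queries = 30, seed = seed)
    reads <- read_set(setNames(
      vapply(1:30, function(i) random_seq(400, seed * 100 + i), character(1)),
      sprintf("q%02d", 1:30)))
    strict <- overlap_fraction(reads, ht, min_identity = 95,
                               min_query_cov = 0.8)
    loose <- overlap_fraction(reads, ht, min_identity = 50,
                              min_query_cov = 0.05)
    expect_lte(strict, loose)
    expect_gte(strict, 0)
    expect_lte(loose, 1)
  }
})
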