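test_that("distance hit filter applies strict >70% identity and >100 bp rules", {
  ht <- make_hits(qseqid = c("q1", "q2", "q3", "q4", "q5"),
                  pident = c(70.0, 71, 75, 95, 60),
                  length = c(150, 100, 150, 300, 400))
  kept <- filter_distance_hits(ht)
  # 70.0% removed (strict), 71%/100bp removed (length strict)
  expect_identical(kept$qseqid, c("q3", "q4"))
  expect_identical(nrow(filter_distance_hits(make_hits("q", pident = 75,
                                                       length = 150))), 1L)
})

test_that("distance hit filter equals a brute-force scan on random tables", {
  for (seed in 1:5) {
    ht <- random_hits(80, seed = seed)
    kept <- filter_distance_hits(ht)
    expect_identical(nrow(kept), sum(ht$pident > 70 & ht$length > 100))
  }
})

test_that("total bit score follows the selection policy", {
  expect_identical(total_bit_score(hit_table()), 0)
  two <- make_hits(qseqid = c("q1", "q1"), sseqid = c("s1", "s2"),
                   bitscore = c(50, 40))
  expect_equal(total_bit_score(two, "best-per-query"), 50)
  expect_equal(total_bit_score(two, "best-per-pair"), 90)
  expect_equal(total_bit_score(two, "all-hsps"), 90)
  three <- make_hits(qseqid = c("q1", "q2", "q3"), bitscore = c(50, 60, 70))
  expect_equal(total_bit_score(three), 180)
  expect_error(total_bit_score(three, "unknown-policy"))
})

test_that("the bit-score Jaccard distance matches its closed form", {
  expect_equal(jaccard_distance(100, 100, 100), 0)   # self comparison
  expect_equal(jaccard_distance(0, 100, 100), 1)     # disjoint datasets
  expect_equal(jaccard_distance(50, 100, 100), 2 / 3)
  expect_equal(jaccard_distance(50, 100, 100, form = "dice"), 0.5)
  expect_error(jaccard_distance(150, 100, 100), "inconsistent")
  expect_error(jaccard_distance(50, 0, 100), "positive")
  # uniform rescaling of every bit score leaves the distance unchanged
  for (seed in 1:5) {
    set.seed(seed)
    ab <- runif(1, 0, 80); aa <- runif(1, 80, 200); bb <- runif(1, 80, 200)
    for (scale in c(10, 0.3, 1000)) {
      expect_equal(jaccard_distance(ab * scale, aa * scale, bb * scale),
                   jaccard_distance(ab, aa, bb), tolerance = 1e-12)
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal and in [0,1]", {
  pc <- simulate_paired_communities(0.5, 4, n_reads = 80, seed = 21,
                                    genome_length = 8000)
  dm <- distance_matrix(list(pc$reads_a, pc$reads_b))
  m <- unclass(dm)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(diag(m), setNames(c(0, 0), c("A", "B")))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("a duplicated dataset sits at distance ~0 from itself", {
  g <- simulate_genome(10000, 0.5, seed = 22)
  sim <- simulate_community(list(g), 1, 80, error_rate = 0, seed = 23,
                            label = "X")
  dup <- read_set(setNames(unname(sim$reads$sequences),
                           paste0("dup_", read_ids(sim$reads))), label = "Y")
  dm <- distance_matrix(list(sim$reads, dup))
  expect_lte(dm[1, 2], 0.01)
})

test_that("neighbor joining reproduces closed-form and additive trees", {
  # 3 taxa: d(A,B)=2, d(A,C)=3, d(B,C)=4 -> pendant branches 0.5, 1.5, 2.5
  m <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr <- neighbor_joining(m)
  pend <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(pend[c("A", "B", "C")],
               c(A = 0.5, B = 1.5, C = 2.5))

  # additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:4)) recovered exactly
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr4 <- neighbor_joining(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr4))[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  # AB|CD split present: A,B form a cherry
  cherry <- tr4$edge[, 1][match(match(c("A", "B"), tr4$tip.label),
                                tr4$edge[, 2])]
  expect_identical(cherry[1], cherry[2])

  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B")))),
               "at least 3")
  bad <- m; bad[1, 2] <- 9
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("negative NJ branch lengths are clamped to zero", {
  m <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 10,
                1, 1, 0, 1,
                10, 10, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(m) # strongly non-additive
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick export round-trips and honors the outgroup", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, LETTERS[1:4])
  expect_equal(as.matrix(ape::cophenetic.phylo(back))[LETTERS[1:4], LETTERS[1:4]],
               as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]],
               tolerance = 1e-9)

  write_newick(tr, f, outgroup = "D")
  rooted <- ape::read.tree(f)
  root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(match("D", rooted$tip.label) %in% root_children)
  expect_error(write_newick(tr, f, outgroup = "Z"), "outgroup")
})

test_that("distance matrix TSV round-trips", {
  m <- matrix(c(0, 0.25, 0.25, 0), 2,
              dimnames = list(c("X", "Y"), c("X", "Y")))
  dm <- structure(m, class = c("DistanceMatrix", class(m)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f)
  back <- read_distance_matrix(f)
  expect_equal(unclass(back), m, tolerance = 1e-9)
  # lower-triangle export is parseable text with one row per label
  f2 <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, f2, lower_triangle = TRUE)
  expect_identical(length(readLines(f2)), 3L)
})
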