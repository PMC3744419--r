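test_that("percent identity matches direct examples and is symmetric", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100.0)
  expect_equal(percent_identity("ACGT", "ACGA"), 75.0)
  expect_error(percent_identity("", "ACGT"), "non-empty")
  # positional-mismatch oracle: substitutions only, no indels planted
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- rand_dna(200)
      b <- a
      pos <- sample(200, 10)
      for (p in pos) {
        substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(a, p, p)), 1)
      }
      oracle <- round(100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]), 1)
      expect_equal(percent_identity(a, b), oracle)
      expect_equal(percent_identity(b, a), percent_identity(a, b))
    }
  })
  expect_lt(percent_identity("AAAAAAAA", "AAAAAAAT"), 100)
})

test_that("find_te_hits locates planted copies and classifies completeness", {
  te <- toy_te(len = 568L)
  genome <- paste0(rand_dna(700, 50), te$sequence, rand_dna(700, 51))
  hits <- find_te_hits(genome, list(te))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 700L)
  expect_equal(hits$end, 700L + 568L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$completeness, "intact")

  # negative control: no planted copy, no hits
  expect_equal(nrow(find_te_hits(rand_dna(5000, 52), list(te))), 0L)
  expect_error(find_te_hits(genome, list()), "empty")

  # seeded substitutions: identity equals the ground-truth mutation count
  withr::with_seed(60, {
    mut <- te$sequence
    pos <- sample(30:530, 17)
    for (p in pos) {
      substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(mut, p, p)), 1)
    }
    g2 <- paste0(rand_dna(500), mut, rand_dna(500))
    h2 <- find_te_hits(g2, list(te))
    expect_equal(nrow(h2), 1L)
    expect_equal(h2$identity, round(100 * (568 - length(unique(pos))) / 568, 1))
  })

  # 3' fragment of the element: fractured_3
  frag <- substr(te$sequence, 568 - 288 + 1, 568)
  g3 <- paste0(rand_dna(400, 53), frag, rand_dna(400, 54))
  h3 <- find_te_hits(g3, list(te))
  expect_equal(h3$completeness, "fractured_3")
  expect_equal(h3$end - h3$start, 288L)

  # 12 bp missing from the 5' TIR still counts as a matched terminus
  trunc <- substr(te$sequence, 13, 568)
  g4 <- paste0(rand_dna(400, 55), trunc, rand_dna(400, 56))
  h4 <- find_te_hits(g4, list(te))
  expect_true(h4$matched_5)
  expect_equal(h4$completeness, "intact")
  expect_identical(classify_te_hit(list(cons_start = 12L, cons_end = 568L,
                                        start = 0L, end = 556L), te),
                   "intact")

  # minus-strand copy is found with consensus coordinates mapped back
  g5 <- paste0(rand_dna(300, 57), reverse_complement(te$sequence),
               rand_dna(300, 58))
  h5 <- find_te_hits(g5, list(te))
  expect_equal(h5$strand, "-")
  expect_equal(h5$cons_start, 0L)
  expect_equal(h5$cons_end, 568L)
})

test_that("flank extraction respects strand and contig edges", {
  g <- rand_dna(60, 70)
  hit <- list(start = 10L, end = 20L, strand = "+")
  fl <- extract_flanks(g, hit, 5L)
  expect_identical(fl$flank5, substr(g, 6, 10))
  expect_identical(fl$flank3, substr(g, 21, 25))
  hitm <- list(start = 10L, end = 20L, strand = "-")
  flm <- extract_flanks(g, hitm, 5L)
  expect_identical(flm$flank5, reverse_complement(substr(g, 21, 25)))
  expect_identical(flm$flank3, reverse_complement(substr(g, 6, 10)))
  edge <- extract_flanks(g, list(start = 2L, end = 20L, strand = "+"), 100L)
  expect_true(edge$trunc5)
  expect_equal(nchar(edge$flank5), 2L)
})

test_that("candidate pairing requires one-sided flank homology within 100 kb", {
  te <- toy_te(len = 300L)
  # RET-style plant: shared downstream flanks only
  pl <- plant_ret_duplication(rand_dna(20000, 80), te, 5000L, 400L, 0.02,
                              seed = 81)
  hits <- find_te_hits(pl$genome, list(te))
  expect_equal(nrow(hits), 2L)
  pairs <- pair_candidates(hits, pl$genome)
  expect_equal(nrow(pairs), 1L)
  expect_identical(pairs$homologous_end, "3prime")

  # two independent copies with random flanks: no pair
  g2 <- paste0(rand_dna(2000, 82), te$sequence, rand_dna(3000, 83),
               te$sequence, rand_dna(2000, 84))
  h2 <- find_te_hits(g2, list(te))
  expect_equal(nrow(pair_candidates(h2, g2)), 0L)

  # full-locus tandem repeat: both flanks homologous, excluded
  block <- paste0(rand_dna(200, 85), te$sequence, rand_dna(200, 86))
  g3 <- paste0(rand_dna(1000, 87), block, block, rand_dna(1000, 88))
  h3 <- find_te_hits(g3, list(te))
  expect_equal(nrow(h3), 2L)
  expect_equal(nrow(pair_candidates(h3, g3)), 0L)

  # lowering the flank identity threshold never loses pairs
  for (thr in c(95, 90, 85, 80, 70)) {
    n_hi <- nrow(pair_candidates(hits, pl$genome,
                                 scan_config(flank_min_identity = thr)))
    n_lo <- nrow(pair_candidates(hits, pl$genome,
                                 scan_config(flank_min_identity = thr - 10)))
    expect_gte(n_lo, n_hi)
  }
})

test_that("validation enforces completeness of the duplicated unit", {
  te <- toy_te(len = 300L)
  pl <- plant_ret_duplication(rand_dna(20000, 90), te, 6000L, 500L, 0,
                              seed = 91)
  hits <- find_te_hits(pl$genome, list(te))
  pairs <- pair_candidates(hits, pl$genome)
  v <- validate_candidate(pl$genome, pairs[1, ], hits)
  expect_equal(v$reason, "")
  expect_equal(v$call$repeat_identity, 100)
  expect_equal(v$call$unit_len, 500L)
  co <- pl$entry$coordinates
  expect_equal(v$call$repeat1_start, co$repeat1_start)
  expect_equal(v$call$repeat2_end, co$repeat2_end)

  # half-matching second copy is rejected as incomplete
  g <- half_dup_genome(te)
  h <- find_te_hits(g, list(te))
  p <- pair_candidates(h, g)
  expect_equal(nrow(p), 1L)
  v2 <- validate_candidate(g, p[1, ], h)
  expect_null(v2$call)
  expect_identical(v2$reason, "incomplete_duplication")
})

test_that("TSD patterns separate RET products from NAHR decoys", {
  te <- toy_te(len = 300L)
  pl <- plant_ret_duplication(rand_dna(15000, 95), te, 4000L, 300L, 0.01,
                              seed = 96)
  rep <- scan_genome(pl$genome, list(te))
  expect_equal(nrow(rep$calls), 1L)
  expect_identical(rep$calls$tsd_class, "ret_consistent")
  expect_identical(rep$calls$tsd_a_left, pl$entry$tsd_seqs$t1)
  expect_identical(rep$calls$tsd_b_left, pl$entry$tsd_seqs$t2)

  nh <- plant_nahr_decoy(rand_dna(15000, 97), te, 4000L, 300L, seed = 98)
  repn <- scan_genome(nh$genome, list(te))
  expect_gte(nrow(repn$calls), 1L)
  expect_true(all(repn$calls$tsd_class == "nahr_like"))

  ex <- plant_excised_junction(rand_dna(15000, 99), te, 4000L, 300L, seed = 100)
  repe <- scan_genome(ex$genome, list(te))
  expect_equal(nrow(repe$calls), 0L)
})

test_that("scanning the reverse complement mirrors the calls", {
  te <- toy_te(len = 300L)
  pl <- plant_ret_duplication(rand_dna(12000, 101), te, 3000L, 250L, 0.02,
                              seed = 102)
  fwd <- scan_genome(pl$genome, list(te))
  n <- nchar(pl$genome$sequence)
  rcg <- seq_record("rc", reverse_complement(pl$genome$sequence))
  rev <- scan_genome(rcg, list(te))
  expect_equal(nrow(rev$calls), nrow(fwd$calls))
  expect_identical(rev$calls$tsd_class, fwd$calls$tsd_class)
  expect_equal(sort(c(n - rev$calls$repeat2_end, n - rev$calls$repeat1_start)),
               sort(c(fwd$calls$repeat1_start, fwd$calls$repeat2_end)))
  expect_true(all(rev$hits$strand == "-"))
})

test_that("external tabular hits can stand in for the internal search", {
  te <- toy_te(len = 300L)
  g <- paste0(rand_dna(500, 110), te$sequence, rand_dna(500, 111))
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "hits.tsv")
  write.table(data.frame("toyTE", "seq", 100.0, 300L, 1L, 300L, 501L, 800L),
              tab, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  h <- read_external_hits(tab, list(toyTE = te))
  expect_equal(h$start, 500L)
  expect_equal(h$end, 800L)
  expect_identical(h$completeness, "intact")
})
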