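test_that("random background is seeded, GC-controlled, and alphabet-bound", {
  a <- random_background(1000, 0.5, seed = 7)
  b <- random_background(1000, 0.5, seed = 7)
  expect_identical(a$sequence, b$sequence)
  big <- random_background(100000, 0.47, seed = 8)
  gc <- mean(strsplit(big$sequence, "")[[1]] %in% c("G", "C"))
  # binomial bound: observed GC within 3 sd of the target
  expect_lt(abs(gc - 0.47), 3 * sqrt(0.47 * 0.53 / 100000))
  at_only <- random_background(10, 0, seed = 9)
  expect_true(grepl("^[AT]+$", at_only$sequence))
})

test_that("planted insertions round-trip through the scanner", {
  te <- toy_te(len = 300L)
  g0 <- random_background(8000, 0.5, seed = 10)
  pl <- plant_te_insertion(g0, te, 4000L)
  co <- pl$entry$coordinates
  hits <- find_te_hits(pl$genome, list(te))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, co$te1_start)
  expect_equal(hits$end, co$te1_end)
  expect_identical(hits$completeness, "intact")
  # the TSD appears once on each side of the element
  s <- pl$genome$sequence
  t1 <- pl$entry$tsd_seqs$t1
  expect_identical(substr(s, co$te1_start - 7, co$te1_start), t1)
  expect_identical(substr(s, co$te1_end + 1, co$te1_end + 8), t1)
  # a single insertion never yields a duplication call
  expect_equal(nrow(scan_genome(pl$genome, list(te))$calls), 0L)
})

test_that("planted divergence and measured repeat identity agree", {
  te <- toy_te(len = 300L)
  # the 1.26 kb unit at 4% divergence: repeat identity ~ 96%
  pl <- plant_ret_duplication(random_background(20000, 0.5, seed = 20),
                              te, 8000L, 1260L, 0.04, seed = 21)
  rep <- scan_genome(pl$genome, list(te))
  expect_equal(nrow(rep$calls), 1L)
  expect_lt(abs(rep$calls$repeat_identity - 96), 1)
  # zero divergence: exact copies
  pl0 <- plant_ret_duplication(random_background(20000, 0.5, seed = 22),
                               te, 8000L, 500L, 0, seed = 23)
  rep0 <- scan_genome(pl0$genome, list(te))
  expect_equal(rep0$calls$repeat_identity, 100)
  expect_error(plant_ret_duplication(random_background(1000, 0.5, seed = 1),
                                     te, 500L, 100L, 0.5, seed = 2),
               "copy_divergence")
})

test_that("fractured-element duplications are planted and recovered", {
  te <- toy_te(name = "zm24like", len = 904L)
  pl <- plant_ret_duplication(random_background(20000, 0.5, seed = 30),
                              te, 9000L, 120L, 0, seed = 31,
                              fractured = list(end = "3prime", length = 288L))
  hits <- find_te_hits(pl$genome, list(te))
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$completeness == "fractured_3"))
  expect_true(all(hits$end - hits$start == 288L))
  rep <- scan_genome(pl$genome, list(te))
  expect_equal(nrow(rep$calls), 1L)
  expect_identical(rep$calls$tsd_class, "ret_consistent")
  expect_identical(rep$calls$homologous_end, "5prime")
  co <- pl$entry$coordinates
  expect_equal(rep$calls$repeat1_start, co$repeat1_start)
  expect_equal(rep$calls$repeat2_end, co$repeat2_end)
})

test_that("NAHR decoys and excised junctions behave as planted", {
  te <- toy_te(len = 300L)
  g <- random_background(40000, 0.5, seed = 40)
  d1 <- plant_nahr_decoy(g, te, 8000L, 250L, seed = 41)
  d2 <- plant_ret_duplication(d1$genome, te, 25000L, 400L, 0.02, seed = 42)
  rep <- scan_genome(d2$genome, list(te))
  expect_equal(sum(rep$calls$tsd_class == "ret_consistent"), 1L)
  expect_gte(sum(rep$calls$tsd_class == "nahr_like"), 1L)
  # the RET call is at the planted RET locus, not the decoy
  ret_call <- rep$calls[rep$calls$tsd_class == "ret_consistent", ]
  expect_equal(ret_call$repeat1_start, d2$entry$coordinates$repeat1_start)

  # small-unit decoy still yields three hits
  d3 <- plant_nahr_decoy(random_background(10000, 0.5, seed = 43), te,
                         4000L, 66L, seed = 44)
  expect_equal(nrow(find_te_hits(d3$genome, list(te))), 3L)

  ex <- plant_excised_junction(random_background(15000, 0.5, seed = 45), te,
                               5000L, 400L, seed = 46)
  repe <- scan_genome(ex$genome, list(te))
  expect_equal(nrow(repe$calls), 0L)
  # repeat copies remain >= 95% identical (verified by direct alignment)
  co <- ex$entry$coordinates
  s <- ex$genome$sequence
  u1 <- substr(s, co$repeat1_start + 1, co$repeat1_end)
  u2len <- co$repeat1_end - co$repeat1_start
  u2 <- substr(s, co$repeat1_end + 1, co$repeat1_end + u2len)
  expect_gte(percent_identity(u1, u2), 95)
  # footprint is within 2 edits of the perfect t2|t1 junction
  expect_true(ex$entry$footprint %in% c("sub1", "sub2", "del1", "del2"))
})

test_that("benchmark generation is deterministic and correctly sized", {
  cfg <- benchmark_config(genome_length = 150000L, n_ret = 2, n_nahr = 1,
                          n_excised = 1, n_insertions = 1,
                          unit_max = 500L)
  b1 <- generate_benchmark(cfg, seed = 5)
  b2 <- generate_benchmark(cfg, seed = 5)
  expect_identical(b1$genome$sequence, b2$genome$sequence)
  expect_identical(b1$manifest, b2$manifest)
  expect_length(b1$manifest$events, 5L)
  types <- vapply(b1$manifest$events, `[[`, "", "event_type")
  expect_equal(sum(types == "ret_duplication"), 2L)
  # every planted coordinate lies within the genome
  n <- nchar(b1$genome$sequence)
  for (e in b1$manifest$events) {
    expect_true(all(unlist(e$coordinates) >= 0 & unlist(e$coordinates) <= n))
  }
  # a different seed changes the genome
  b3 <- generate_benchmark(cfg, seed = 6)
  expect_false(identical(b1$genome$sequence, b3$genome$sequence))
  # too-small genome errors
  expect_error(generate_benchmark(benchmark_config(genome_length = 30000L),
                                  seed = 1), "too small")
  # written artifacts round-trip
  dir <- withr::local_tempdir()
  write_benchmark(b1, dir)
  expect_true(all(file.exists(file.path(dir, c("genome.fa", "truth.json",
                                               "truth.bed")))))
  back <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(back[[1]]$sequence, b1$genome$sequence)
})

test_that("benchmark scan recovers planted truth on a reduced config", {
  cfg <- benchmark_config(genome_length = 300000L, n_ret = 3, n_nahr = 1,
                          n_excised = 1, n_insertions = 1)
  b <- generate_benchmark(cfg, seed = 11)
  rep <- scan_genome(b$genome, b$te_library)
  sc <- score_scan(rep, b$manifest)
  expect_equal(sc$n_ret_exact, 3L)
  expect_equal(sc$recall, 1)
  expect_equal(sc$false_ret_calls, 0L)
  expect_equal(sc$decoy_ret_calls, 0L)
  expect_equal(sc$excised_calls, 0L)
})
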