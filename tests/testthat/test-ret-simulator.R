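test_that("insert_element applies the target-site-duplication rule", {
  te0 <- transposon_def("mini", "toy", "GGAGG", 1, 1, 0)
  cm <- chromatid_model(seq_record("c", "AAATTT"))
  te0$sequence <- "GG"  # 2 bp toy element, no TSD
  te0$tir5_len <- 0L; te0$tir3_len <- 0L
  out <- insert_element(cm, te0, target_site(cm, 3, 0))
  expect_identical(out$record$sequence, "AAAGGTTT")

  te <- transposon_def("mini2", "toy", "CCCC", 1, 1, 3)
  cm2 <- chromatid_model(seq_record("c", "ACGTACGT"))
  out2 <- insert_element(cm2, te, target_site(cm2, 2, 3))
  expect_identical(out2$record$sequence, "ACGTACCCCGTACGT")

  # an 8 bp target appears once on each side of the element
  seq3 <- paste0(rand_dna(20, 3), "GCGCTTTA", rand_dna(20, 4))
  cm3 <- chromatid_model(seq_record("c", seq3))
  te3 <- toy_te()
  out3 <- insert_element(cm3, te3, target_site(cm3, 20, 8))
  expect_identical(
    out3$record$sequence,
    paste0(substr(seq3, 1, 28), te3$sequence, "GCGCTTTA", substr(seq3, 29, 48)))
  # inserting into the element is rejected
  expect_error(insert_element(out3, te3, target_site(out3, 30, 8)),
               "overlaps an existing")
})

test_that("excision restores the target region to within a 1-2 bp footprint", {
  cm <- chromatid_model(seq_record("c", rand_dna(120, 5)))
  te <- toy_te()
  ins <- insert_element(cm, te, target_site(cm, 60, 8))
  perfect <- excise_element(ins, "toyTE", footprint_model = "perfect")
  expect_identical(perfect$chromatid$record$sequence, cm$record$sequence)
  expect_identical(perfect$footprint, "")

  # determinism under a fixed seed
  a <- excise_element(ins, "toyTE", seed = 11)
  b <- excise_element(ins, "toyTE", seed = 11)
  expect_identical(a$chromatid$record$sequence, b$chromatid$record$sequence)
  expect_identical(a$footprint, b$footprint)

  # brute-force edit-distance oracle: footprint junction within 2 edits
  for (s in 1:12) {
    fp <- excise_element(ins, "toyTE", seed = s)
    d <- utils::adist(fp$chromatid$record$sequence, cm$record$sequence)[1, 1]
    expect_lte(d, 2)
    expect_gte(d, 1)
  }

  # element without terminus annotations is rejected
  bare <- ins
  bare$features <- bare$features[bare$features$kind != "te_terminus", ]
  expect_error(excise_element(bare, "toyTE", footprint_model = "perfect"),
               "terminus annotations")
})

test_that("ret_transpose reproduces the junction-assembly oracle on toys", {
  # fixed-size toy mirroring the 21 bp worked example (segments 4/3/3/5/2, tsd 2)
  toy <- make_toy_ret(seed = 2, lens = c(bgL = 4, te1 = 3, circ = 3,
                                         te2 = 5, mid = 2, bgR = 2),
                      tsd_len = 2L)
  out <- ret_transpose(toy$chromatid, toy$event)
  expect_identical(out$duplication_product$record$sequence, toy$expected$dup)
  expect_identical(out$deletion_product$record$sequence, toy$expected$del)
  expect_identical(out$circle$sequence, toy$expected$circle)
  expect_equal(seq_length(out$duplication_product), 30L)
  expect_equal(seq_length(out$deletion_product), 11L)
  expect_equal(nchar(out$circle$sequence), 3L)
  expect_equal(seq_length(out$duplication_product) +
                 seq_length(out$deletion_product) + nchar(out$circle$sequence),
               2 * seq_length(toy$chromatid) + 2)

  # randomized toys: oracle identity, TSD triple equality, copy counts
  for (s in 3:20) {
    toy <- make_toy_ret(seed = s)
    out <- ret_transpose(toy$chromatid, toy$event)
    expect_identical(out$duplication_product$record$sequence, toy$expected$dup)
    expect_identical(out$deletion_product$record$sequence, toy$expected$del)
    expect_identical(out$circle$sequence, toy$expected$circle)
    # triple equality: target == duplication junction == deletion junction
    expect_identical(unique(out$junctions$tsd), toy$expected$tsd)
    # exactly 2 direct copies of the unit, 0 inverted
    dupseq <- out$duplication_product$record$sequence
    hits <- gregexpr(toy$expected$unit, dupseq, fixed = TRUE)[[1]]
    expect_length(hits[hits > 0], 2L)
    rc_hits <- gregexpr(reverse_complement(toy$expected$unit), dupseq,
                        fixed = TRUE)[[1]]
    expect_identical(as.integer(rc_hits[1]), -1L)
  }
})

test_that("event geometry is validated", {
  toy <- make_toy_ret(seed = 30)
  # target inside the element pair interval
  bad_target <- target_site(toy$chromatid, toy$coords$cut5 + 2L, 8L)
  ev <- ret_event_spec("TE1_3prime", "TE2_5prime", bad_target)
  expect_error(ret_transpose(toy$chromatid, ev), "inside the transposon pair")
  # swapped donors (5' element left of 3' element) are rejected
  ev2 <- ret_event_spec("TE2_5prime", "TE1_3prime", toy$event$target)
  expect_error(ret_transpose(toy$chromatid, ev2), "expected")
})

test_that("dicentric join mode classifies a non-viable pair conserving sequence", {
  toy <- make_toy_ret(seed = 31)
  ev <- ret_event_spec("TE1_3prime", "TE2_5prime", toy$event$target,
                       join_mode = "dicentric")
  out <- ret_transpose(toy$chromatid, ev)
  expect_false(out$viable)
  tot <- nchar(out$dicentric$sequence) + nchar(out$acentric$sequence) +
    nchar(out$circle$sequence)
  expect_equal(tot, 2 * seq_length(toy$chromatid) + 8)
})

test_that("products serialize to FASTA/GFF3/JSON", {
  toy <- make_toy_ret(seed = 40)
  out <- ret_transpose(toy$chromatid, toy$event)
  dir <- withr::local_tempdir()
  write_ret_products(out, dir)
  expect_true(all(file.exists(file.path(dir, c("duplication.fa", "deletion.fa",
                                               "circle.fa", "event.json",
                                               "duplication.gff3")))))
  log <- jsonlite::read_json(file.path(dir, "event.json"))
  expect_identical(log$side, "proximal")
  expect_length(log$junctions, 2L)
})
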