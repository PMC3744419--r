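test_that("amplicon prediction follows primer-placement arithmetic", {
  withr::with_seed(120, {
    fwd <- primer_def("F", rand_dna(20))
    rev <- primer_def("R", rand_dna(20))
    tmpl <- paste0(rand_dna(100), fwd$sequence, rand_dna(300),
                   reverse_complement(rev$sequence), rand_dna(100))
    amps <- predict_amplicons(tmpl, list(fwd, rev))
    expect_equal(nrow(amps), 1L)
    expect_equal(amps$start, 100L)
    expect_equal(amps$end, 100L + 20L + 300L + 20L)
    expect_equal(amps$length, amps$end - amps$start)
    # no product when the reverse site precedes the forward site
    tmpl2 <- paste0(rand_dna(100), reverse_complement(rev$sequence),
                    rand_dna(300), fwd$sequence, rand_dna(100))
    expect_equal(nrow(predict_amplicons(tmpl2, list(fwd, rev))), 0L)
    # a 3'-terminal mismatch kills binding; one 5' mismatch does not
    tmpl3 <- tmpl
    substr(tmpl3, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                       substr(tmpl3, 120, 120))[1]
    expect_equal(nrow(predict_amplicons(tmpl3, list(fwd, rev))), 0L)
    tmpl4 <- tmpl
    substr(tmpl4, 101, 101) <- setdiff(c("A", "C", "G", "T"),
                                       substr(tmpl4, 101, 101))[1]
    expect_equal(nrow(predict_amplicons(tmpl4, list(fwd, rev))), 1L)
    # amplicon set is invariant under reverse complement (mirrored coords)
    n <- nchar(tmpl)
    rc <- reverse_complement(tmpl)
    back <- predict_amplicons(rc, list(fwd, rev))
    expect_equal(nrow(back), 1L)
    expect_equal(back$start, n - amps$end)
    expect_equal(back$end, n - amps$start)
  })
})

test_that("the fixture PCR panel reproduces the published pattern", {
  fx <- cached_fixture()
  out <- cached_proximal()
  pr <- fixture_primers()
  n_products <- function(tmpl, a, b) {
    nrow(predict_amplicons(tmpl, pr[c(a, b)]))
  }
  # progenitor: target-site product only
  expect_equal(n_products(fx, "primer1", "primer2"), 1L)
  expect_equal(n_products(fx, "primer1", "Ac5"), 0L)
  expect_equal(n_products(fx, "primer2", "Ac3"), 0L)
  # duplication allele: junction product 1+Ac5 appears, deletion assay silent
  dup <- out$duplication_product
  expect_equal(n_products(dup, "primer1", "Ac5"), 1L)
  expect_equal(n_products(dup, "primer1", "primer2"), 1L)
  expect_equal(n_products(dup, "primer2", "Ac3"), 0L)
  # deletion allele: deletion junction product 2+Ac3 only
  del <- out$deletion_product
  expect_equal(n_products(del, "primer2", "Ac3"), 1L)
  expect_equal(n_products(del, "primer1", "Ac5"), 0L)
  expect_equal(n_products(del, "primer1", "primer2"), 0L)
})

test_that("excision PCR amplifies only after excision, with footprint-length scatter", {
  out <- cached_proximal()
  dup <- out$duplication_product
  pr <- fixture_primers()
  # pre-excision: the 4565 bp element keeps primers 1+3 out of range
  expect_equal(nrow(predict_amplicons(dup, pr[c("primer1", "primer3")])), 0L)
  jte <- find_junction_te(dup)
  expect_equal(jte$end - jte$start, 4565L)
  prods <- simulate_excision_pcr(dup, jte, pr[c("primer1", "primer3")],
                                 n_events = 6, seed = 5)
  expect_gte(nrow(prods), 6L)
  # product lengths differ only by the 0-2 bp footprint deletions
  base <- max(prods$length)
  expect_true(all(base - prods$length <= 2))
  subs <- prods[grepl("sub", prods$footprint), ]
  expect_true(all(subs$length == base))
  dels <- prods[grepl("del", prods$footprint), ]
  if (nrow(dels)) {
    expect_true(all(base - dels$length ==
                      as.integer(substr(dels$footprint, 4, 4))))
  }
  # seeded reruns are identical
  again <- simulate_excision_pcr(dup, jte, pr[c("primer1", "primer3")],
                                 n_events = 6, seed = 5)
  expect_identical(prods, again)
  # primers that do not flank the element are rejected
  expect_error(simulate_excision_pcr(dup, jte, pr[c("primer1", "primer2")],
                                     n_events = 1, seed = 1),
               "do not flank")
})

test_that("virtual digest conserves length and respects methylation", {
  fx <- cached_fixture()
  probe <- probe15_sequence()
  d <- virtual_southern(fx, probe_seq = probe)
  expect_equal(sum(d$length), seq_length(fx))
  # ignoring methylation can only add cut sites
  d2 <- virtual_southern(fx, probe_seq = probe, respect_methylation = FALSE)
  expect_gte(nrow(d2), nrow(d))
  expect_equal(sum(d2$length), seq_length(fx))
  # with the mask off, cut count equals the brute-force substring scan
  occ <- gregexpr("GTCGAC", fx$record$sequence, fixed = TRUE)[[1]]
  expect_equal(nrow(d2), length(occ) + 1L)
  # the methylated site is the one uncut difference
  expect_equal(nrow(d2), nrow(d) + 1L)
  expect_error(virtual_southern(fx, "GT", probe), ">= 4 bp")
  expect_error(virtual_southern(fx, probe_seq = "ACGTACGT"), ">= 50")
})

test_that("digest bands reproduce the progenitor/duplication/deletion blots", {
  fx <- cached_fixture()
  out <- cached_proximal()
  probe <- probe15_sequence()
  bands <- function(x) {
    b <- southern_bands(virtual_southern(x, probe_seq = probe))
    stats::setNames(b$multiplicity, b$length)
  }
  prog <- bands(fx)
  expect_identical(prog, c("5451" = 1L, "2693" = 1L, "1269" = 2L))
  dup <- bands(out$duplication_product)
  expect_equal(unname(dup["2693"]), 2L)
  expect_equal(unname(dup["5451"]), 1L)
  del <- bands(out$deletion_product)
  expect_false("2693" %in% names(del))
  expect_false("5451" %in% names(del))
  # the fAc fragment shifts to the fixture's ~12 kb deletion fragment
  shifted <- as.integer(names(del)[!names(del) %in% c("1269")])
  expect_length(shifted, 1L)
  expect_gt(shifted, 11000L)
  expect_lt(shifted, 13000L)
  # homolog fixture contributes its 1075 bp band
  ww <- bands(build_p1ww_fixture())
  expect_identical(ww, c("1075" = 1L))
})

test_that("paralog copy ratios report duplication extent", {
  fx <- cached_fixture()
  ww <- build_p1ww_fixture()
  out <- cached_proximal()
  # progenitor / p1-ww diploid: p2/p1 = 2/1
  expect_identical(copy_ratio(list(fx, ww)), c(p2 = 2L, p1 = 1L))
  # duplication not spanning p2: 2/2
  expect_identical(copy_ratio(list(out$duplication_product, ww)),
                   c(p2 = 2L, p1 = 2L))
  # duplication spanning p2: 3/2
  fx2 <- cached_fixture()
  big <- ret_transpose(fx2, p1_ret_event(fx2, "beyond_p2"))
  expect_identical(copy_ratio(list(big$duplication_product, ww)),
                   c(p2 = 3L, p1 = 2L))
  # single chromatid counts alone; absent markers error
  expect_identical(copy_ratio(list(fx)), c(p2 = 1L, p1 = 1L))
  expect_error(copy_ratio(list(fx), "nope_a", "nope_b"), "absent")
})
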