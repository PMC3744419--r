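# Shared in-code fixtures for the test suite. Everything is generated
# programmatically; no binary data.

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A toy RET-competent chromatid built from named segments, with the expected
# products assembled independently by explicit fragment joining (the
# junction-assembly oracle). Segment layout (left to right):
#   bgL | TE1 (3' terminus at right edge) | circ | TE2 (5' terminus at left
#   edge) | mid | tsd (8 bp unless stated) | bgR
# The centromere sits at the right end, so the default target is proximal.
make_toy_ret <- function(seed = 1, lens = NULL, tsd_len = 8L) {
  withr::with_seed(seed, {
    if (is.null(lens)) {
      lens <- c(bgL = sample(30:80, 1), te1 = sample(25:60, 1),
                circ = sample(15:50, 1), te2 = sample(25:60, 1),
                mid = sample(10:60, 1), bgR = sample(30:80, 1))
    }
    segs <- lapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    })
    tsd <- paste(sample(c("A", "C", "G", "T"), tsd_len, replace = TRUE),
                 collapse = "")
    P <- paste0(segs$bgL, segs$te1, segs$circ, segs$te2, segs$mid, tsd,
                segs$bgR)
    c1 <- nchar(segs$bgL)                     # TE1 start
    cut3 <- c1 + nchar(segs$te1)              # TE1 end = 3' cut
    cut5 <- cut3 + nchar(segs$circ)           # TE2 start = 5' cut
    te2_end <- cut5 + nchar(segs$te2)
    tp <- te2_end + nchar(segs$mid)           # target position
    fe <- rbind(
      retdup::features(chrom = "toy", start = c1, end = cut3,
                       kind = "te_instance", name = "TE1"),
      retdup::features(chrom = "toy", start = cut3 - 5L, end = cut3,
                       kind = "te_terminus", name = "TE1_3prime",
                       attrs = "terminus=3prime;te=TE1"),
      retdup::features(chrom = "toy", start = cut5, end = te2_end,
                       kind = "te_instance", name = "TE2"),
      retdup::features(chrom = "toy", start = cut5, end = cut5 + 5L,
                       kind = "te_terminus", name = "TE2_5prime",
                       attrs = "terminus=5prime;te=TE2"),
      retdup::features(chrom = "toy", start = tp, end = tp + tsd_len,
                       kind = "target_site", name = "target"))
    cm <- chromatid_model(seq_record("toy", P), fe,
                          centromere_pos = nchar(P))
    event <- ret_event_spec("TE1_3prime", "TE2_5prime",
                            target_site(cm, tp, tsd_len))
    # independent junction-assembly oracle
    unit <- paste0(segs$te2, segs$mid, tsd)
    expected <- list(
      dup = paste0(segs$bgL, segs$te1, segs$circ, unit, unit, segs$bgR),
      del = paste0(segs$bgL, segs$te1, tsd, segs$bgR),
      circle = segs$circ, unit = unit, tsd = tsd)
    list(chromatid = cm, event = event, expected = expected, segs = segs,
         coords = list(cut3 = cut3, cut5 = cut5, tp = tp))
  })
}

# Small deterministic TE for scanner tests: 200 bp with 11 bp TIRs.
toy_te <- function(name = "toyTE", len = 200L, seed = 99) {
  withr::with_seed(seed, {
    s <- rand_dna(len)
    tir <- rand_dna(11L)
    substr(s, 1, 11) <- tir
    substr(s, len - 10L, len) <- retdup::reverse_complement(tir)
    transposon_def(name, paste0(name, "_fam"), s, 11L, 11L, 8L)
  })
}

# A one-sided-homology locus whose second repeat "copy" matches only the
# first half of the inter-element unit (fails the completeness filter).
half_dup_genome <- function(te) {
  withr::with_seed(92, {
    t1 <- rand_dna(8); t2 <- rand_dna(8)
    core <- rand_dna(400)
    half <- paste0(substr(core, 1, 200), rand_dna(208))
    paste0(rand_dna(2000), t1, te$sequence, t1, core, t2, te$sequence,
           t1, half, rand_dna(2000))
  })
}

# Fixture + proximal outcome, computed once per test file load.
cached_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- build_p1_fixture(seed = 1)
    fx
  }
})

cached_proximal <- local({
  out <- NULL
  function() {
    if (is.null(out)) {
      fx <- cached_fixture()
      out <<- ret_transpose(fx, p1_ret_event(fx, "proximal"))
    }
    out
  }
})
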