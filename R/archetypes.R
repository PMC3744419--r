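# Synthetic stand-ins for the three genomic duplication archetypes recovered
# by the B73 scan: constructed loci with the published dimensions (element
# sizes, repeat lengths, identities, TSD patterns), used to exercise the
# scanner on each structural class. The sequences themselves are synthetic.

# Mutate with n substitutions confined to [lo, hi) (0-based), keeping the
# edges clean so hit boundaries stay breakpoint-exact.
.mutate_subs_range <- function(seq, n_sub, edge = 20L) {
  n <- nchar(seq)
  lo <- edge; hi <- n - edge
  if (n_sub <= 0L || hi <= lo) return(seq)
  pos <- sample(seq.int(lo + 1L, hi), min(n_sub, hi - lo))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

.insert_bases <- function(seq, n_ins, at) {
  paste0(substr(seq, 1L, at), .random_dna(n_ins, 0.5),
         substr(seq, at + 1L, nchar(seq)))
}

#' Synthetic dhAT-like element library for the archetype loci
#'
#' Three deterministic consensi sized like the elements of the three scan
#' archetypes: a 700 bp dhAT-Zm1-like, a 568 bp dhAT-Zm13-like and a 904 bp
#' dhAT-Zm24-like element (synthetic sequences; only the dimensions are
#' modelled).
#'
#' @return Named list of [transposon_def()].
#' @export
archetype_te_library <- function() {
  withr::with_seed(.FIXTURE_MASTER_SEED + 3L, {
    lens <- c(dhATZm1 = 700L, dhATZm13 = 568L, dhATZm24 = 904L)
    out <- lapply(names(lens), function(nm) {
      L <- lens[[nm]]
      s <- .random_dna(L, 0.5)
      tir <- .random_dna(11L, 0.5)
      substr(s, 1L, 11L) <- tir
      substr(s, L - 10L, L) <- reverse_complement(tir)
      transposon_def(nm, paste0(nm, "_family"), s, 11L, 11L, 8L)
    })
    names(out) <- names(lens)
    out
  })
}

#' Build the three archetype loci (synthetic)
#'
#' One background record per archetype:
#' * `arch_chr1`: element-leading duplication by two ~95%-identical 700 bp
#'   elements; repeat copies 147 and 148 bp, ~93% identical (one indel).
#' * `arch_chr7`: element-leading duplication by a 568 bp intact element and
#'   a copy missing 12 bp of its 5' TIR; repeat copies 1262 and 1257 bp,
#'   ~96% identical.
#' * `arch_chr6`: element-trailing (distal-mechanism) duplication by two
#'   3'-terminal fragments (288 and 289 bp of a 904 bp element); repeat
#'   copies 116 and 118 bp, ~99% identical.
#'
#' In every locus the pre-existing element carries a matched two-sided 8 bp
#' TSD and the RET-joint element matches it on exactly one side.
#'
#' @param seed Integer seed for backgrounds and divergence placement.
#' @return List with `genomes` (named list of [seq_record()]), `te_library`,
#'   and `expected` (the planted measurements).
#' @export
build_archetype_loci <- function(seed = 1L) {
  lib <- archetype_te_library()
  withr::with_seed(seed, {
    mk_bg <- function(id, n) seq_record(id, .random_dna(n, 0.47), "synthetic")

    # arch_chr1: units 147/148, elements 95% identical (700 bp)
    bg1 <- mk_bg("arch_chr1", 4000L)
    t1 <- .substr0(bg1$sequence, 1500L, 1508L)
    t2 <- .draw_other_tsd(t1)
    core1 <- .random_dna(147L - 16L, 0.5)
    core2 <- .insert_bases(.mutate_subs_range(core1, 9L, edge = 10L), 1L, 60L)
    tea <- lib$dhATZm1$sequence
    teb <- .mutate_subs_range(tea, 35L, edge = 20L)
    cass1 <- paste0(tea, t1, core1, t2, teb, t1, core2, t2)
    g1 <- seq_record("arch_chr1", .splice(bg1$sequence, 1508L, cass1))

    # arch_chr7: units 1262/1257, intact 568 bp element + 12 bp TIR-deleted copy
    bg7 <- mk_bg("arch_chr7", 8000L)
    s1 <- .substr0(bg7$sequence, 3000L, 3008L)
    s2 <- .draw_other_tsd(s1)
    u1core <- .random_dna(1262L - 16L, 0.5)
    # second copy: 5 bp shorter, ~4% diverged
    u2core <- .mutate_subs_range(substr(u1core, 1L, nchar(u1core) - 5L),
                                 45L, edge = 10L)
    zea <- lib$dhATZm13$sequence
    zeb <- .mutate_subs_range(substr(zea, 13L, nchar(zea)), 25L, edge = 20L)
    cass7 <- paste0(zea, s1, u1core, s2, zeb, s1, u2core, s2)
    g7 <- seq_record("arch_chr7", .splice(bg7$sequence, 3008L, cass7))

    # arch_chr6: element-trailing, 288/289 bp 3' fragments of 904 bp element
    bg6 <- mk_bg("arch_chr6", 4000L)
    r1 <- .substr0(bg6$sequence, 1800L, 1808L)
    r2 <- .draw_other_tsd(r1)
    w1core <- .random_dna(116L - 16L, 0.5)
    w2core <- .insert_bases(w1core, 2L, 50L)
    zm24 <- lib$dhATZm24$sequence
    f2 <- substr(zm24, nchar(zm24) - 289L + 1L, nchar(zm24))
    f1 <- .mutate_subs_range(substr(zm24, nchar(zm24) - 288L + 1L,
                                    nchar(zm24)), 11L, edge = 20L)
    cass6 <- paste0(r2, w1core, r1, f1, r2, w2core, r1, f2)
    g6 <- seq_record("arch_chr6", .splice(bg6$sequence, 1800L, cass6))

    genomes <- list(arch_chr1 = g1, arch_chr7 = g7, arch_chr6 = g6)
    expected <- list(zm13_intact_len = 568L,
                     chr7_first_repeat = 1262L,
                     chr1_first_repeat = 147L,
                     chr6_fragment_lens = c(288L, 289L))
    list(genomes = genomes, te_library = lib, expected = expected)
  })
}
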