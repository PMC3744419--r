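# Synthetic model of the maize P1-ovov454 locus: the p1 gene carrying a
# reversely-oriented fAc/Ac pair in intron 2, with the primers, probe-15
# homology blocks and SalI sites needed by the in-silico diagnostics. The
# sequence itself is synthetic; element sizes, primer sequences, the target
# 8-mer, and the diagnostic fragment sizes match the published locus.

.AC_LEN <- 4565L
.AC_TIR5 <- "TAGGGATGAAA"
.FAC_LEN <- 2039L
.TSD_A_B <- "GCGCTTTA"

.PRIMER_SEQS <- c(
  primer1 = "GCCGAGCGTTCCGTGATCGTGACTC",       # allele-specific (T1)
  primer2 = "CGGGACGCATGTGTGTGCTTGAT",         # allele-specific (T1)
  primer3 = "GCTATCAAACAGGACACGGGAGAGAAT",
  Ac5     = "CCCGTTTCCGTTCCGTTTTCGT",
  Ac3     = "GATTACCGTATTTATCCCGTTCGTTTTC"
)

.SALI <- "GTCGAC"
.FIXTURE_MASTER_SEED <- 20130815L

.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Remove every occurrence of `site` except those starting at `allowed`
# (0-based), mutating one unprotected base per occurrence.
.scrub_sites <- function(seq, site = .SALI, allowed = integer(),
                         protected = NULL) {
  flip <- c(A = "C", C = "A", G = "T", T = "G", N = "A")
  for (iter in 1:25) {
    occ <- gregexpr(site, seq, fixed = TRUE)[[1]]
    if (occ[1] == -1L) return(seq)
    occ0 <- as.integer(occ) - 1L
    occ0 <- setdiff(occ0, allowed)
    if (!length(occ0)) return(seq)
    for (o in occ0) {
      cand <- o:(o + nchar(site) - 1L)
      if (!is.null(protected) && nrow(protected)) {
        inprot <- vapply(cand, function(p) {
          any(p >= protected$start & p < protected$end)
        }, logical(1))
        cand <- cand[!inprot]
      }
      if (!length(cand)) {
        stop("cannot scrub recognition site: all bases protected", call. = FALSE)
      }
      p <- cand[ceiling(length(cand) / 2)]
      base <- substr(seq, p + 1L, p + 1L)
      substr(seq, p + 1L, p + 1L) <- unname(flip[base])
    }
  }
  stop("site scrubbing did not converge", call. = FALSE)
}

#' The packaged Ac element consensus
#'
#' A deterministic synthetic 4565 bp Ac consensus: real Ac length, real 11 bp
#' TIRs, and the outward-facing Ac5/Ac3 primer sites embedded near the 5' and
#' 3' ends; the remainder is fixed pseudo-random sequence.
#'
#' @return A [transposon_def()] named `"Ac"`, family `"hAT"`.
#' @export
ac_element <- function() {
  seq <- withr::with_seed(.FIXTURE_MASTER_SEED, .random_dna(.AC_LEN))
  tir3 <- reverse_complement(.AC_TIR5)
  substr(seq, 1L, 11L) <- .AC_TIR5
  substr(seq, .AC_LEN - 10L, .AC_LEN) <- tir3
  # Ac5 anneals to the minus strand near the 5' end, pointing outward.
  rc5 <- reverse_complement(.PRIMER_SEQS[["Ac5"]])
  substr(seq, 31L, 30L + nchar(rc5)) <- rc5
  # Ac3 anneals to the plus strand near the 3' end, pointing outward.
  a3 <- .PRIMER_SEQS[["Ac3"]]
  substr(seq, 4446L, 4445L + nchar(a3)) <- a3
  seq <- .scrub_sites(seq, protected = data.frame(
    start = c(0L, .AC_LEN - 11L, 30L, 4445L),
    end = c(11L, .AC_LEN, 30L + nchar(rc5), 4445L + nchar(a3))))
  transposon_def("Ac", "hAT", seq, tir5_len = 11L, tir3_len = 11L,
                 tsd_len = 8L)
}

#' The packaged p1 probe-15 sequence
#'
#' Deterministic synthetic 600 bp probe; the fixture plants exact sub-blocks
#' of it at the loci where the real probe hybridises.
#'
#' @return Character scalar (600 bp).
#' @export
probe15_sequence <- function() {
  withr::with_seed(.FIXTURE_MASTER_SEED + 1L, .scrub_sites(.random_dna(600L)))
}

#' Primer set of the p1 fixture
#'
#' The shared primers (3, Ac5, Ac3) and the T1-allele-specific primers 1 and 2.
#'
#' @return Named list of [primer_def()] objects.
#' @export
fixture_primers <- function() {
  anchors <- c(primer1 = "proximal flank (distal of target)",
               primer2 = "proximal flank (proximal of target)",
               primer3 = "between Ac and p1 exon 2",
               Ac5 = "Ac 5' end, outward", Ac3 = "Ac/fAc 3' end, outward")
  out <- lapply(names(.PRIMER_SEQS), function(nm) {
    primer_def(nm, .PRIMER_SEQS[[nm]], anchors[[nm]])
  })
  names(out) <- names(.PRIMER_SEQS)
  out
}

#' TE library of the p1 fixture
#' @return Named list with the packaged Ac [transposon_def()].
#' @export
fixture_te_library <- function() {
  list(Ac = ac_element())
}

#' Build the P1-ovov454 progenitor fixture
#'
#' Constructs a ~29 kb chromatid modelling the progenitor allele: distal
#' flank, p1 exon 3, fAc (3' terminus facing Ac), the inter-element segment,
#' Ac (5' terminus facing fAc), exons 2 and 1, and the proximal flank carrying
#' the default a/b target site `GCGCTTTA`, a scaled-down p2 paralog, the
#' primer-1/2/3/Ac5/Ac3 anchor sites, four probe-15 homology blocks, and SalI
#' sites placed so the progenitor digest yields probe-hybridising fragments of
#' exactly 5451, 2693 and 1269 bp (the 1269 bp fragment twice). One SalI site
#' (inside the 5451 bp fragment) carries a methylation mark and does not cut.
#' The centromere is at the proximal (right) end.
#'
#' @param params Named list of segment-length overrides (see source for the
#'   available names); overrides that produce overlapping features error.
#' @param seed Integer seed for the background sequence.
#' @return A [chromatid_model()] named `"P1ovov454"`.
#' @export
build_p1_fixture <- function(params = list(), seed = 1L) {
  p <- list(left_bg = 400L, distal_target_at = 150L,
            fragA_pre = 300L, fragA_post = 763L,
            f2_x1 = 200L, exon3_len = 300L, f2_x2 = 100L,
            f2_x3a = 1200L, f2_x3b = 1280L, circ1 = 120L,
            circ2 = 494L, gap_ac_p3 = 678L, p3_exon2 = 150L,
            exon_gap = 100L, exon1_len = 150L, post_exon1 = 800L,
            f4_pre = 400L, f4_post = 2087L,
            f5_pre = 300L, primer1_to_target = 775L, target_to_primer2 = 250L,
            f5_post = 6397L,
            f6_pre = 400L, f6_post = 663L,
            tail_pre = 3000L, p2_len = 300L, p2_to_target = 200L,
            tail_post = 292L)
  if (length(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown)) stop("unknown fixture params: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    p[names(params)] <- lapply(params, as.integer)
  }
  ac <- ac_element()
  fac_seq <- substr(ac$sequence, .AC_LEN - .FAC_LEN + 1L, .AC_LEN)
  probe <- probe15_sequence()
  id <- "P1ovov454"

  withr::with_seed(seed, {
    parts <- character()
    feats <- NULL
    cur <- 0L
    sali_at <- integer()
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      cur <<- cur + nchar(s)
    }
    addf <- function(start, end, kind, name, strand = "+", attrs = "") {
      feats <<- rbind(feats, .feat(start, end, kind, name, strand = strand,
                                   attrs = attrs, chrom = id))
    }
    add_sali <- function(methylated = FALSE) {
      sali_at <<- c(sali_at, cur)
      addf(cur, cur + 6L, "restriction_site", "SalI")
      if (methylated) addf(cur, cur + 6L, "methylation_mark", "SalI_methylated")
      add(.SALI)
    }
    bg <- function(n) add(.random_dna(n))

    # distal flank with the distal target site
    stopifnot(p$distal_target_at + 8L < p$left_bg)
    bg(p$distal_target_at)
    addf(cur, cur + 8L, "target_site", "target_distal")
    bg(p$left_bg - p$distal_target_at)
    # distal 1269 bp probe fragment
    add_sali()
    bg(p$fragA_pre)
    addf(cur, cur + 200L, "probe", "probe15_block_distal")
    add(substr(probe, 1L, 200L))
    bg(p$fragA_post)
    # 5451 bp fragment: exon 3, probe block, methylated site, fAc
    add_sali()
    bg(p$f2_x1)
    addf(cur, cur + p$exon3_len, "exon", "p1_exon3", attrs = "gene=p1")
    bg(p$exon3_len)
    bg(p$f2_x2)
    addf(cur, cur + 200L, "probe", "probe15_block_fAc")
    add(substr(probe, 201L, 400L))
    bg(p$f2_x3a)
    add_sali(methylated = TRUE)
    bg(p$f2_x3b)
    fac_start <- cur
    addf(cur, cur + .FAC_LEN, "te_instance", "fAc",
         attrs = .attrs_make(te = "fAc", family = "hAT", fragment = "3prime"))
    addf(cur + .FAC_LEN - 11L, cur + .FAC_LEN, "te_terminus", "fAc_3prime",
         attrs = .attrs_make(terminus = "3prime", te = "fAc"))
    addf(cur + 1919L, cur + 1947L, "primer", "Ac3_site_fAc")
    add(fac_seq)
    bg(p$circ1)
    # SalI inside the inter-element (circle) segment
    add_sali()
    bg(p$circ2)
    ac_start <- cur
    addf(cur, cur + .AC_LEN, "te_instance", "Ac",
         attrs = .attrs_make(te = "Ac", family = "hAT"))
    addf(cur, cur + 11L, "te_terminus", "Ac_5prime",
         attrs = .attrs_make(terminus = "5prime", te = "Ac"))
    addf(cur + .AC_LEN - 11L, cur + .AC_LEN, "te_terminus", "Ac_3prime",
         attrs = .attrs_make(terminus = "3prime", te = "Ac"))
    addf(cur + 30L, cur + 52L, "primer", "Ac5_site", strand = "-")
    addf(cur + 4445L, cur + 4473L, "primer", "Ac3_site")
    add(ac$sequence)
    bg(p$gap_ac_p3)
    addf(cur, cur + 27L, "primer", "primer3", strand = "-")
    add(reverse_complement(.PRIMER_SEQS[["primer3"]]))
    addf(cur, cur + p$p3_exon2, "exon", "p1_exon2", attrs = "gene=p1")
    bg(p$p3_exon2)
    bg(p$exon_gap)
    addf(cur, cur + p$exon1_len, "exon", "p1_exon1", attrs = "gene=p1")
    addf(cur, cur + p$exon1_len, "label", "p1", attrs = "gene=p1")
    bg(p$exon1_len)
    bg(p$post_exon1)
    # 2693 bp fragment proximal to Ac (inside the duplicated unit)
    add_sali()
    bg(p$f4_pre)
    addf(cur, cur + 200L, "probe", "probe15_block_proximal")
    add(substr(probe, 401L, 600L))
    bg(p$f4_post)
    # fragment with primer 1, the a/b target, primer 2
    add_sali()
    bg(p$f5_pre)
    addf(cur, cur + 25L, "primer", "primer1")
    add(.PRIMER_SEQS[["primer1"]])
    bg(p$primer1_to_target)
    target_pos <- cur
    addf(cur, cur + 8L, "target_site", "target_a_b")
    add(.TSD_A_B)
    bg(p$target_to_primer2)
    addf(cur, cur + 23L, "primer", "primer2", strand = "-")
    add(reverse_complement(.PRIMER_SEQS[["primer2"]]))
    bg(p$f5_post)
    # proximal 1269 bp probe fragment
    add_sali()
    bg(p$f6_pre)
    addf(cur, cur + 200L, "probe", "probe15_block_p1_proximal")
    add(substr(probe, 1L, 200L))
    bg(p$f6_post)
    add_sali()
    # tail: scaled p2 paralog, far-proximal target, centromere at the end
    bg(p$tail_pre)
    addf(cur, cur + p$p2_len, "label", "p2", attrs = "gene=p2")
    bg(p$p2_len)
    bg(p$p2_to_target)
    addf(cur, cur + 8L, "target_site", "target_beyond_p2")
    bg(p$tail_post)

    seq <- paste(parts, collapse = "")
    prot <- feats[feats$kind %in% c("primer", "te_instance", "probe",
                                    "target_site", "restriction_site"), ,
                  drop = FALSE]
    seq <- .scrub_sites(seq, allowed = sali_at, protected = prot)
    cm <- chromatid_model(seq_record(id, seq, "synthetic P1-ovov454 model"),
                          feats, centromere_pos = nchar(seq))
    viol <- validate_chromatid(cm)
    ov <- .overlap_violations(feats)
    if (length(c(viol, ov))) {
      stop("fixture params produce an invalid chromatid: ",
           paste(c(viol, ov), collapse = "; "), call. = FALSE)
    }
    attr(cm, "key_positions") <- list(fac_start = fac_start,
                                      fac_end = fac_start + .FAC_LEN,
                                      ac_start = ac_start,
                                      ac_end = ac_start + .AC_LEN,
                                      target = target_pos)
    cm
  })
}

# Overlap checks for fixture parameter overrides: sequence-bearing features
# must not collide (annotation-only kinds may nest).
.overlap_violations <- function(feats) {
  solid <- feats[feats$kind %in% c("exon", "te_instance", "primer", "probe",
                                   "restriction_site", "target_site"), ,
                 drop = FALSE]
  solid <- solid[order(solid$start), , drop = FALSE]
  v <- character()
  if (nrow(solid) > 1L) {
    for (i in 2:nrow(solid)) {
      prev <- solid[i - 1L, ]
      this <- solid[i, ]
      inside_te <- prev$kind == "te_instance" && this$end <= prev$end
      if (this$start < prev$end && !inside_te) {
        v <- c(v, sprintf("features '%s' and '%s' overlap", prev$name, this$name))
      }
      if (inside_te) solid[i, ] <- prev  # keep the enclosing TE as 'prev'
    }
  }
  v
}

#' Build the p1-ww[4Co63] homolog fixture
#'
#' Small synthetic model of the tester chromosome: no p1 gene, one p2 paralog,
#' and a single probe-15-hybridising SalI fragment of exactly 1075 bp.
#'
#' @param seed Integer seed for the background sequence.
#' @return A [chromatid_model()] named `"p1ww4Co63"`.
#' @export
build_p1ww_fixture <- function(seed = 2L) {
  probe <- probe15_sequence()
  id <- "p1ww4Co63"
  withr::with_seed(seed, {
    parts <- character(); feats <- NULL; cur <- 0L; sali_at <- integer()
    add <- function(s) { parts[[length(parts) + 1L]] <<- s; cur <<- cur + nchar(s) }
    addf <- function(start, end, kind, name, strand = "+", attrs = "") {
      feats <<- rbind(feats, .feat(start, end, kind, name, strand = strand,
                                   attrs = attrs, chrom = id))
    }
    add(.random_dna(300L))
    sali_at <- c(sali_at, cur); addf(cur, cur + 6L, "restriction_site", "SalI")
    add(.SALI)
    add(.random_dna(400L))
    addf(cur, cur + 160L, "probe", "probe15_block_ww")
    add(substr(probe, 1L, 160L))
    add(.random_dna(1069L - 400L - 160L))
    sali_at <- c(sali_at, cur); addf(cur, cur + 6L, "restriction_site", "SalI")
    add(.SALI)
    add(.random_dna(300L))
    addf(cur, cur + 300L, "label", "p2", attrs = "gene=p2")
    add(.random_dna(300L))
    add(.random_dna(100L))
    seq <- paste(parts, collapse = "")
    prot <- feats[feats$kind %in% c("probe", "restriction_site"), , drop = FALSE]
    seq <- .scrub_sites(seq, allowed = sali_at, protected = prot)
    chromatid_model(seq_record(id, seq, "synthetic p1-ww[4Co63] model"),
                    feats, centromere_pos = nchar(seq))
  })
}

#' Default RET event on the p1 fixture
#'
#' Pairs the fAc 3' terminus with the Ac 5' terminus and targets one of the
#' fixture's annotated target sites.
#'
#' @param fixture Chromatid from [build_p1_fixture()].
#' @param target `"proximal"` (the a/b site, `GCGCTTTA`), `"distal"` (a site
#'   in the distal flank), `"beyond_p2"` (a proximal site beyond the p2
#'   paralog), or a [target_site()] object.
#' @param join_mode Passed to [ret_event_spec()].
#' @return A [ret_event_spec()].
#' @export
p1_ret_event <- function(fixture, target = c("proximal", "distal", "beyond_p2"),
                         join_mode = "duplication_deletion") {
  if (!inherits(target, "target_site")) {
    target <- match.arg(target)
    nm <- switch(target, proximal = "target_a_b", distal = "target_distal",
                 beyond_p2 = "target_beyond_p2")
    fe <- fixture$features
    row <- fe[fe$kind == "target_site" & fe$name == nm, ]
    if (!nrow(row)) stop("fixture lacks target feature ", nm, call. = FALSE)
    target <- target_site(fixture, row$start[1], 8L)
  }
  ret_event_spec("fAc_3prime", "Ac_5prime", target, join_mode = join_mode)
}
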