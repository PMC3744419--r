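# Genome scanning for RET-signature tandem direct duplications: locate
# hAT-family element copies, classify intact/fractured, compare 100 bp flanks,
# pair candidates, validate the tandem repeat structure, and classify the
# target-site-duplication pattern as RET-consistent vs NAHR-like.

#' Scanner configuration
#'
#' All thresholds of the scanning procedure with their defaults: seed length
#' `k = 12` for the internal k-mer seeded search, hits shorter than 100 bp or
#' below 80% identity discarded, 100 bp flanks, candidate pairs within 100 kb,
#' flank homology at >= 80% identity over >= 80% of the flank, repeat copies
#' >= 85% identity, terminal windows matched to within 15 bp (`edge_slack`,
#' accommodating TIR truncations), and exact (0-mismatch) 8 bp TSD matching.
#'
#' @param ... Named overrides of the defaults; unknown names are an error.
#' @return Named list of parameters.
#' @export
scan_config <- function(...) {
  cfg <- list(k = 12L, min_length = 100L, min_identity = 80,
              diag_tol = 50L, max_gap = 1000L, min_seeds = 2L,
              edge_slack = 15L, flank_len = 100L,
              max_distance = 100000L, flank_min_identity = 80,
              flank_min_cov = 0.8, repeat_min_identity = 85,
              tsd_len = 8L, tsd_max_mismatch = 0L, max_amplicon = 6000L)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown scan config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

# Substitution matrix over {A,C,G,T,N}: match +1, mismatch -1, any pairing
# involving N is a mismatch.
.nuc_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1); identity is matches over alignment columns (gaps included),
#' in percent to one decimal. `N` never counts as a match.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Numeric percent identity in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("percent_identity requires non-empty sequences", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = .nuc_matrix(),
    gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == sa & pa != "-" & pa != "N")
  round(100 * matches / length(pa), 1)
}

.hit_cols <- function() {
  data.frame(te_name = character(), family = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             completeness = character(), identity = numeric(),
             cons_start = integer(), cons_end = integer(),
             matched_5 = logical(), matched_3 = logical(),
             n_seeds = integer(), stringsAsFactors = FALSE)
}

# Seed-and-extend search of one query (one strand) against one sequence.
.search_one <- function(subject, query_seq, k, diag_tol, max_gap) {
  L <- nchar(query_seq)
  if (L < k) return(NULL)
  n_k <- L - k + 1L
  kmers <- substring(query_seq, seq_len(n_k), seq_len(n_k) + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  mi <- Biostrings::matchPDict(pd, subject)
  st <- Biostrings::startIndex(mi)
  lens <- lengths(st)
  if (sum(lens) == 0L) return(NULL)
  c0 <- rep((seq_len(n_k)[keep]) - 1L, lens)
  g0 <- unlist(st, use.names = FALSE) - 1L
  o <- order(g0, c0)
  g0 <- g0[o]; c0 <- c0[o]
  d <- g0 - c0
  brk <- c(FALSE, diff(g0) > max_gap | abs(diff(d)) > diag_tol)
  grp <- cumsum(brk)
  lapply(split(seq_along(g0), grp), function(ii) {
    list(gstart = min(g0[ii]), gend = max(g0[ii]) + k,
         qstart = min(c0[ii]), qend = max(c0[ii]) + k,
         n_seeds = length(ii))
  })
}

#' Classify a TE hit as intact or fractured
#'
#' A terminus is "matched" when the aligned consensus interval reaches the
#' corresponding consensus end to within `edge_slack` bp (default 15,
#' accommodating small TIR truncations). Hits with both termini are `intact`;
#' one terminus and length > 100 bp, `fractured_5`/`fractured_3` (naming the
#' matched end); otherwise `fragment` (discarded upstream).
#'
#' @param hit One hit row (list or 1-row data.frame) with `cons_start`,
#'   `cons_end` and genomic `start`, `end`.
#' @param te_def The [transposon_def()] of the hit.
#' @param tolerances List with `edge_slack` (and `min_length`).
#' @return Character label.
#' @export
classify_te_hit <- function(hit, te_def, tolerances = list()) {
  slack <- if (!is.null(tolerances$edge_slack)) tolerances$edge_slack else 15L
  min_len <- if (!is.null(tolerances$min_length)) tolerances$min_length else 100L
  L <- nchar(te_def$sequence)
  m5 <- hit$cons_start <= slack
  m3 <- (L - hit$cons_end) <= slack
  len <- hit$end - hit$start
  if (m5 && m3) "intact"
  else if (m5 && len > min_len) "fractured_5"
  else if (m3 && len > min_len) "fractured_3"
  else "fragment"
}

#' Find hAT-family transposon copies in a genome
#'
#' k-mer seeded, diagonal-chained local search of every library consensus
#' against both strands, followed by per-hit global alignment to the matched
#' consensus interval for the identity estimate and intact/fractured
#' classification. Overlapping hits are resolved in favour of the
#' higher-identity (then longer) hit; unmatched fragments (< both termini)
#' and hits below `min_length`/`min_identity` are dropped.
#'
#' @param genome A [chromatid_model()], [seq_record()], character sequence, or
#'   a list of these (scanned per record).
#' @param te_library Named list of [transposon_def()] (e.g.
#'   [load_te_library()]); must be non-empty.
#' @param config [scan_config()] list.
#' @return data.frame of hits: `te_name`, `family`, `chrom`, 0-based `start`,
#'   `end`, `strand`, `completeness`, `identity`, consensus interval,
#'   terminus flags, `n_seeds`.
#' @export
find_te_hits <- function(genome, te_library, config = scan_config()) {
  if (!length(te_library)) stop("empty TE library", call. = FALSE)
  genomes <- if (is.list(genome) && !inherits(genome, c("seq_record", "chromatid_model"))) {
    genome
  } else list(genome)
  out <- .hit_cols()
  for (g in genomes) {
    seq <- .as_sequence(g)
    chrom <- if (inherits(g, "chromatid_model")) g$record$id
             else if (inherits(g, "seq_record")) g$id else "seq"
    subject <- Biostrings::DNAString(seq)
    for (te in te_library) {
      L <- nchar(te$sequence)
      for (strand in c("+", "-")) {
        query <- if (strand == "+") te$sequence else reverse_complement(te$sequence)
        clusters <- .search_one(subject, query, config$k, config$diag_tol,
                                config$max_gap)
        for (cl in clusters) {
          if (cl$n_seeds < config$min_seeds) next
          width <- cl$gend - cl$gstart
          if (width < config$min_length) next
          if (strand == "+") {
            cs <- cl$qstart; ce <- cl$qend
          } else {
            cs <- L - cl$qend; ce <- L - cl$qstart
          }
          gseq <- extract_region(seq, cl$gstart, cl$gend, strand)
          cseq <- .substr0(te$sequence, cs, ce)
          ident <- percent_identity(gseq, cseq)
          if (ident < config$min_identity) next
          hit <- list(cons_start = cs, cons_end = ce,
                      start = cl$gstart, end = cl$gend)
          comp <- classify_te_hit(hit, te, list(edge_slack = config$edge_slack,
                                                min_length = config$min_length))
          if (comp == "fragment") next
          out <- rbind(out, data.frame(
            te_name = te$name, family = te$family, chrom = chrom,
            start = cl$gstart, end = cl$gend, strand = strand,
            completeness = comp, identity = ident,
            cons_start = cs, cons_end = ce,
            matched_5 = cs <= config$edge_slack,
            matched_3 = (L - ce) <= config$edge_slack,
            n_seeds = cl$n_seeds, stringsAsFactors = FALSE))
        }
      }
    }
  }
  .resolve_overlaps(out)
}

# Keep the better hit where hits overlap on the same chromosome.
.resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) { rownames(hits) <- NULL; return(hits) }
  o <- order(hits$chrom, -hits$identity, -(hits$end - hits$start))
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    ov <- hits$chrom[prior] == hits$chrom[i] &
      hits$start[prior] < hits$end[i] & hits$end[prior] > hits$start[i]
    if (any(ov)) keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Ingest tabular output of an external search tool
#'
#' Adapter for genome-scale runs: parses a BLAST-style tab-separated table
#' (columns `qseqid sseqid pident length qstart qend sstart send`, 1-based,
#' minus-strand subject intervals given reversed) into the hit table used by
#' the rest of the pipeline.
#'
#' @param path TSV path.
#' @param te_library Library supplying family assignments and lengths.
#' @param config [scan_config()].
#' @return Hit data.frame as from [find_te_hits()].
#' @export
read_external_hits <- function(path, te_library, config = scan_config()) {
  tb <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tb)[1:8] <- c("qseqid", "sseqid", "pident", "length", "qstart",
                      "qend", "sstart", "send")
  out <- .hit_cols()
  for (i in seq_len(nrow(tb))) {
    r <- tb[i, ]
    te <- te_library[[r$qseqid]]
    if (is.null(te)) next
    L <- nchar(te$sequence)
    strand <- if (r$sstart <= r$send) "+" else "-"
    gs <- min(r$sstart, r$send) - 1L
    ge <- max(r$sstart, r$send)
    cs <- r$qstart - 1L
    ce <- r$qend
    hit <- list(cons_start = cs, cons_end = ce, start = gs, end = ge)
    comp <- classify_te_hit(hit, te, list(edge_slack = config$edge_slack,
                                          min_length = config$min_length))
    if (comp == "fragment" || ge - gs < config$min_length ||
        r$pident < config$min_identity) next
    out <- rbind(out, data.frame(
      te_name = te$name, family = te$family, chrom = r$sseqid,
      start = gs, end = ge, strand = strand, completeness = comp,
      identity = r$pident, cons_start = cs, cons_end = ce,
      matched_5 = cs <= config$edge_slack,
      matched_3 = (L - ce) <= config$edge_slack,
      n_seeds = NA_integer_, stringsAsFactors = FALSE))
  }
  .resolve_overlaps(out)
}

#' Extract the flanking segments of a TE hit
#'
#' Returns the 5'-adjacent and 3'-adjacent flanks in TE-consensus orientation
#' (reverse-complemented and swapped for minus-strand hits); flanks truncated
#' at contig edges are flagged.
#'
#' @param genome Sequence carrier for the hit's chromosome.
#' @param hit One hit row.
#' @param flank_len Flank length in bp (default 100).
#' @return List with `flank5`, `flank3`, `trunc5`, `trunc3`.
#' @export
extract_flanks <- function(genome, hit, flank_len = 100L) {
  seq <- .as_sequence(genome)
  n <- nchar(seq)
  left <- .substr0(seq, max(0L, hit$start - flank_len), hit$start)
  right <- .substr0(seq, hit$end, min(n, hit$end + flank_len))
  if (hit$strand == "+") {
    list(flank5 = left, flank3 = right,
         trunc5 = nchar(left) < flank_len, trunc3 = nchar(right) < flank_len)
  } else {
    list(flank5 = reverse_complement(right), flank3 = reverse_complement(left),
         trunc5 = nchar(right) < flank_len, trunc3 = nchar(left) < flank_len)
  }
}

#' Pair TE hits with one-sided flank homology
#'
#' For every same-family, same-strand pair of hits on one chromosome closer
#' than `max_distance` (inner-edge distance), compares the two 5'-adjacent
#' flanks and the two 3'-adjacent flanks; a flank pair is homologous at
#' >= `flank_min_identity`% over >= `flank_min_cov` of `flank_len`. Pairs
#' homologous at exactly one terminal end are retained — the asymmetry that
#' distinguishes an RET duplication from a simple full-locus repeat.
#'
#' @param hits Hit table from [find_te_hits()].
#' @param genome Sequence carrier (or list keyed by chromosome id).
#' @param config [scan_config()].
#' @return data.frame of candidate pairs with hit indices `ia`, `ib` (genome
#'   order), `distance`, `homologous_end`, `flank_identity`.
#' @export
pair_candidates <- function(hits, genome, config = scan_config()) {
  out <- data.frame(ia = integer(), ib = integer(), chrom = character(),
                    distance = integer(), homologous_end = character(),
                    flank_identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) < 2L) return(out)
  min_cov <- config$flank_min_cov * config$flank_len
  for (i in seq_len(nrow(hits) - 1L)) {
    for (j in (i + 1L):nrow(hits)) {
      a <- hits[i, ]; b <- hits[j, ]
      if (a$chrom != b$chrom || a$family != b$family || a$strand != b$strand) next
      if (b$start < a$end) next
      distance <- b$start - a$end
      if (distance >= config$max_distance) next
      fa <- extract_flanks(.genome_for(genome, a$chrom), a, config$flank_len)
      fb <- extract_flanks(.genome_for(genome, b$chrom), b, config$flank_len)
      hom <- c("5prime" = NA_real_, "3prime" = NA_real_)
      for (endname in c("5prime", "3prime")) {
        x <- if (endname == "5prime") fa$flank5 else fa$flank3
        y <- if (endname == "5prime") fb$flank5 else fb$flank3
        if (nchar(x) >= min_cov && nchar(y) >= min_cov) {
          id <- percent_identity(x, y)
          if (id >= config$flank_min_identity) hom[endname] <- id
        }
      }
      if (sum(!is.na(hom)) == 1L) {
        endname <- names(hom)[!is.na(hom)]
        out <- rbind(out, data.frame(
          ia = i, ib = j, chrom = a$chrom, distance = distance,
          homologous_end = endname,
          flank_identity = unname(hom[endname]), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

.genome_for <- function(genome, chrom) {
  if (is.list(genome) && !inherits(genome, c("seq_record", "chromatid_model"))) {
    g <- genome[[chrom]]
    if (is.null(g)) stop("no genome record for ", chrom, call. = FALSE)
    g
  } else genome
}

#' Validate the tandem-duplication structure of a candidate pair
#'
#' Checks the completeness and initiation criteria: the repeat unit is the
#' complete inter-element segment, anchored at the element boundary, and its
#' second copy (the equal-length segment immediately following the second
#' element — or immediately preceding the first element when the homologous
#' flank is the 5'-adjacent one) must match at >= `repeat_min_identity`%
#' end-to-end.
#'
#' @param genome Sequence carrier.
#' @param pair One row of [pair_candidates()] output.
#' @param hits The hit table the pair indexes into.
#' @param config [scan_config()].
#' @return List with `call` (1-row data.frame or `NULL`) and `reason`
#'   (rejection reason code, `""` on success).
#' @export
validate_candidate <- function(genome, pair, hits, config = scan_config()) {
  a <- hits[pair$ia, ]; b <- hits[pair$ib, ]
  g <- .genome_for(genome, a$chrom)
  seq <- .as_sequence(g)
  n <- nchar(seq)
  L1 <- b$start - a$end
  if (L1 <= 0L) return(list(call = NULL, reason = "no_inter_element_segment"))
  downstream <- (a$strand == "+") == (pair$homologous_end == "3prime")
  if (downstream) {
    u1 <- c(a$end, b$start)
    u2 <- c(b$end, b$end + L1)
    if (u2[2] > n) return(list(call = NULL, reason = "incomplete_duplication"))
  } else {
    u1 <- c(a$end, b$start)
    u2 <- c(a$start - L1, a$start)
    if (u2[1] < 0L) return(list(call = NULL, reason = "incomplete_duplication"))
  }
  ident <- percent_identity(.substr0(seq, u1[1], u1[2]),
                            .substr0(seq, u2[1], u2[2]))
  if (ident < config$repeat_min_identity) {
    return(list(call = NULL, reason = "incomplete_duplication"))
  }
  r1 <- if (u1[1] <= u2[1]) u1 else u2
  r2 <- if (u1[1] <= u2[1]) u2 else u1
  call <- data.frame(
    chrom = a$chrom,
    repeat1_start = r1[1], repeat1_end = r1[2],
    repeat2_start = r2[1], repeat2_end = r2[2],
    repeat_identity = ident,
    unit_len = L1, unit_len_excl_tsd = L1 - 2L * config$tsd_len,
    te_a = pair$ia, te_b = pair$ib,
    te_name = a$te_name, family = a$family, strand = a$strand,
    homologous_end = pair$homologous_end,
    flank_identity = pair$flank_identity,
    distance = pair$distance,
    tsd_class = NA_character_, tsd_a_left = NA_character_,
    tsd_a_right = NA_character_, tsd_b_left = NA_character_,
    tsd_b_right = NA_character_, notes = "", stringsAsFactors = FALSE)
  list(call = call, reason = "")
}

.hamming_le <- function(x, y, max_mm) {
  if (nchar(x) != nchar(y)) return(FALSE)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  sum(xs != ys | xs == "N") <= max_mm
}

#' Classify the TSD pattern of a duplication call
#'
#' Extracts the `tsd_len`-mers flanking each element copy. The RET signature:
#' exactly one element of the pair carries a matched two-sided TSD (the
#' pre-duplication insertion) while the other matches that TSD on exactly one
#' side (its other junction is the RET insertion joint). Both elements with
#' matched two-sided TSDs, or a third same-family copy bounding the repeat
#' region, is the NAHR signature; anything else is indeterminate.
#'
#' @param genome Sequence carrier.
#' @param call 1-row call data.frame from [validate_candidate()].
#' @param hits Hit table.
#' @param config [scan_config()].
#' @return The call row with `tsd_class` and the four TSD sequences filled in.
#' @export
classify_tsd_pattern <- function(genome, call, hits, config = scan_config()) {
  a <- hits[call$te_a, ]; b <- hits[call$te_b, ]
  g <- .genome_for(genome, call$chrom)
  seq <- .as_sequence(g)
  n <- nchar(seq)
  tl <- config$tsd_len
  grab <- function(s, e) if (s >= 0L && e <= n) .substr0(seq, s, e) else ""
  aL <- grab(a$start - tl, a$start); aR <- grab(a$end, a$end + tl)
  bL <- grab(b$start - tl, b$start); bR <- grab(b$end, b$end + tl)
  mm <- config$tsd_max_mismatch
  eq <- function(x, y) nzchar(x) && nzchar(y) && .hamming_le(x, y, mm)
  a_paired <- eq(aL, aR)
  b_paired <- eq(bL, bR)

  others <- setdiff(seq_len(nrow(hits)), c(call$te_a, call$te_b))
  third <- FALSE
  if (length(others)) {
    oo <- hits[others, , drop = FALSE]
    same <- oo$chrom == call$chrom & oo$family == a$family
    near <- abs(oo$start - call$repeat2_end) <= tl + 2L |
      abs(oo$end - call$repeat1_start) <= tl + 2L
    third <- any(same & near)
  }

  cls <- "indeterminate"
  if ((a_paired && b_paired) || third) {
    cls <- "nahr_like"
  } else if (xor(a_paired, b_paired)) {
    t_ref <- if (a_paired) aL else bL
    other <- if (a_paired) c(bL, bR) else c(aL, aR)
    nm <- sum(vapply(other, function(x) eq(x, t_ref), logical(1)))
    cls <- if (nm == 1L) "ret_consistent"
           else if (nm == 2L) "nahr_like" else "indeterminate"
  }
  call$tsd_class <- cls
  call$tsd_a_left <- aL; call$tsd_a_right <- aR
  call$tsd_b_left <- bL; call$tsd_b_right <- bR
  call
}

#' Scan a genome for RET-signature tandem duplications
#'
#' Runs the full procedure: find hits, classify completeness, extract flanks,
#' pair candidates with one-sided flank homology, validate the tandem repeat
#' (completeness + initiation), and classify each validated call's TSD
#' pattern.
#'
#' @param genome Sequence carrier or list of records.
#' @param te_library Named list of [transposon_def()].
#' @param config [scan_config()].
#' @return List of class `scan_report`: `hits`, `pairs`, `calls`,
#'   `rejections` (data.frame of rejected pairs with reasons), `summary`.
#' @export
scan_genome <- function(genome, te_library, config = scan_config()) {
  hits <- find_te_hits(genome, te_library, config)
  pairs <- pair_candidates(hits, genome, config)
  calls <- NULL
  rejections <- data.frame(ia = integer(), ib = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      v <- validate_candidate(genome, pairs[i, ], hits, config)
      if (is.null(v$call)) {
        rejections <- rbind(rejections,
                            data.frame(ia = pairs$ia[i], ib = pairs$ib[i],
                                       reason = v$reason,
                                       stringsAsFactors = FALSE))
      } else {
        calls <- rbind(calls, classify_tsd_pattern(genome, v$call, hits, config))
      }
    }
  }
  calls <- .dedupe_calls(calls)
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), repeat1_start = integer(),
                        repeat1_end = integer(), repeat2_start = integer(),
                        repeat2_end = integer(), repeat_identity = numeric(),
                        unit_len = integer(), unit_len_excl_tsd = integer(),
                        te_a = integer(), te_b = integer(),
                        te_name = character(), family = character(),
                        strand = character(), homologous_end = character(),
                        flank_identity = numeric(), distance = integer(),
                        tsd_class = character(), tsd_a_left = character(),
                        tsd_a_right = character(), tsd_b_left = character(),
                        tsd_b_right = character(), notes = character(),
                        stringsAsFactors = FALSE)
  }
  fam_counts <- if (nrow(hits)) table(hits$family) else table(character())
  summary <- list(
    n_hits = nrow(hits),
    hits_per_family = as.list(fam_counts),
    n_pairs = nrow(pairs),
    n_validated = nrow(calls),
    n_rejected = nrow(rejections),
    n_ret_consistent = sum(calls$tsd_class == "ret_consistent"),
    n_nahr_like = sum(calls$tsd_class == "nahr_like"))
  structure(list(hits = hits, pairs = pairs, calls = calls,
                 rejections = rejections, summary = summary),
            class = "scan_report")
}

# Overlapping calls (e.g. the two element pairs of a three-copy locus):
# keep all, but order by position and drop exact duplicates; ties among
# overlapping candidate pairs are resolved by flank identity then position.
.dedupe_calls <- function(calls) {
  if (is.null(calls) || !nrow(calls)) return(calls)
  calls <- calls[order(calls$chrom, -calls$flank_identity, calls$repeat1_start), ,
                 drop = FALSE]
  key <- paste(calls$chrom, calls$repeat1_start, calls$repeat2_end)
  calls <- calls[!duplicated(key), , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$repeat1_start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' @export
print.scan_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<scan_report> %d hits, %d candidate pairs, %d calls ",
                     "(%d ret_consistent, %d nahr_like)\n"),
              s$n_hits, s$n_pairs, s$n_validated, s$n_ret_consistent,
              s$n_nahr_like))
  invisible(x)
}

#' Write a scan report to disk
#'
#' Emits `calls.tsv` (one row per duplication call), `repeats.bed` (BED6 of
#' the repeat copies), and `summary.json` (hit and filter-stage counts).
#'
#' @param report A `scan_report` from [scan_genome()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- report$calls
  write.table(calls, file.path(dir, "calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(calls) && nrow(calls)) {
    bed <- features(chrom = rep(calls$chrom, 2L),
                    start = c(calls$repeat1_start, calls$repeat2_start),
                    end = c(calls$repeat1_end, calls$repeat2_end),
                    strand = rep(calls$strand, 2L), kind = "label",
                    name = paste0(rep(calls$te_name, 2L), "_repeat",
                                  rep(1:2, each = nrow(calls))))
    write_features_bed(bed, file.path(dir, "repeats.bed"))
  } else {
    writeLines(character(), file.path(dir, "repeats.bed"))
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
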