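# In-silico counterparts of the molecular assays used to verify alleles:
# junction PCR, excision PCR, restriction digest with probe hybridisation
# (virtual Southern), and paralog copy-ratio.

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param sequence Primer sequence, 5'->3', length >= 15.
#' @param anchor Free-text genomic anchor description.
#' @return Object of class `primer_def`.
#' @export
primer_def <- function(name, sequence, anchor = "") {
  sequence <- .check_dna(sequence, allow_n = FALSE,
                         what = sprintf("primer '%s'", name))
  if (nchar(sequence) < 15L) stop("primer must be >= 15 nt", call. = FALSE)
  structure(list(name = name, sequence = sequence, anchor = anchor),
            class = "primer_def")
}

#' PCR parameters
#' @param max_amplicon Longest product considered amplifiable (default
#'   6000 bp; chosen so a full Ac element between two primers blocks
#'   amplification until it excises).
#' @param three_prime_exact Bases at the primer 3' end requiring a perfect
#'   match (default 12).
#' @param max_mismatch Mismatches tolerated outside the 3' window (default 2).
#' @return Named list.
#' @export
pcr_params <- function(max_amplicon = 6000L, three_prime_exact = 12L,
                       max_mismatch = 2L) {
  list(max_amplicon = max_amplicon, three_prime_exact = three_prime_exact,
       max_mismatch = max_mismatch)
}

# Binding sites of one primer on one template.
# Forward sites: primer matches the + strand, 3' end pointing right.
# Reverse sites: primer matches the - strand, 3' end pointing left.
.primer_sites <- function(subject, primer, params) {
  L <- nchar(primer$sequence)
  w <- min(params$three_prime_exact, L)
  out <- list(fwd = integer(), rev = integer())
  m <- Biostrings::matchPattern(primer$sequence, subject,
                                max.mismatch = params$max_mismatch)
  if (length(m)) {
    tail_p <- substr(primer$sequence, L - w + 1L, L)
    ok <- vapply(seq_along(m), function(i) {
      s <- as.character(m[[i]])
      substr(s, L - w + 1L, L) == tail_p
    }, logical(1))
    out$fwd <- BiocGenerics::start(m)[ok] - 1L  # 0-based starts
  }
  rc <- reverse_complement(primer$sequence)
  m2 <- Biostrings::matchPattern(rc, subject, max.mismatch = params$max_mismatch)
  if (length(m2)) {
    head_rc <- substr(rc, 1L, w)  # primer 3' end, leftmost on the template
    ok2 <- vapply(seq_along(m2), function(i) {
      s <- as.character(m2[[i]])
      substr(s, 1L, w) == head_rc
    }, logical(1))
    out$rev <- BiocGenerics::end(m2)[ok2]  # 0-based half-open ends
  }
  out
}

#' Predict PCR amplicons on a template
#'
#' Enumerates all products of the given primers (two or more, as in a
#' multiplexed reaction): every forward binding site combined with every
#' reverse binding site downstream of it, up to `max_amplicon`. A primer
#' binds where its 3'-terminal window matches perfectly and at most
#' `max_mismatch` mismatches occur elsewhere.
#'
#' @param template Sequence carrier.
#' @param primers List of [primer_def()] (a pair or a multiplex set).
#' @param params [pcr_params()].
#' @return data.frame of amplicons sorted by length: `template`, `fwd_primer`,
#'   `rev_primer`, 0-based `start`, `end`, `length`.
#' @export
predict_amplicons <- function(template, primers, params = pcr_params()) {
  g <- .genome_seq_id(template)
  subject <- Biostrings::DNAString(g$seq)
  if (inherits(primers, "primer_def")) primers <- list(primers)
  sites <- lapply(primers, .primer_sites, subject = subject, params = params)
  names(sites) <- vapply(primers, `[[`, "", "name")
  out <- data.frame(template = character(), fwd_primer = character(),
                    rev_primer = character(), start = integer(),
                    end = integer(), length = integer(),
                    stringsAsFactors = FALSE)
  for (fp in names(sites)) {
    for (rp in names(sites)) {
      for (fs in sites[[fp]]$fwd) {
        for (re in sites[[rp]]$rev) {
          len <- re - fs
          if (len > 0L && len <= params$max_amplicon) {
            out <- rbind(out, data.frame(
              template = g$id, fwd_primer = fp, rev_primer = rp,
              start = fs, end = re, length = len, stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate excision PCR
#'
#' Models the short-cycle PCR that detects somatic excision: the element
#' between the primers is too long to amplify across, but each independent
#' excision event brings the primers into range, with product lengths varying
#' by the 0-2 bp footprint. Samples `n_events` independent excisions and
#' predicts products on each post-excision template.
#'
#' @param template A [chromatid_model()] carrying the element.
#' @param te_instance Name of the `te_instance` feature.
#' @param primers List of [primer_def()] flanking the element.
#' @param footprint_model Passed to [excise_element()].
#' @param n_events Number of independent excisions to sample.
#' @param seed Integer seed.
#' @param params [pcr_params()].
#' @return data.frame of products with `event`, `footprint`, amplicon columns.
#' @export
simulate_excision_pcr <- function(template, te_instance, primers,
                                  footprint_model = "default", n_events = 2L,
                                  seed = 1L, params = pcr_params()) {
  fe <- template$features
  row <- if (is.character(te_instance)) {
    fe[fe$kind == "te_instance" & fe$name == te_instance, , drop = FALSE][1, ]
  } else te_instance
  perfect <- excise_element(template, te_instance, footprint_model = "perfect")
  check <- predict_amplicons(perfect$chromatid, primers, params)
  # the diagnostic product must span the excision junction
  check <- check[check$start < row$start & check$end > row$start, , drop = FALSE]
  if (!nrow(check)) {
    stop("primers do not flank the element within max_amplicon",
         call. = FALSE)
  }
  out <- NULL
  for (i in seq_len(n_events)) {
    ex <- excise_element(template, te_instance,
                         footprint_model = footprint_model,
                         seed = seed + i - 1L)
    amps <- predict_amplicons(ex$chromatid, primers, params)
    if (nrow(amps)) {
      amps$event <- i
      amps$footprint <- if (nzchar(ex$footprint)) ex$footprint else "perfect"
      out <- rbind(out, amps)
    }
  }
  if (is.null(out)) {
    out <- data.frame(template = character(), fwd_primer = character(),
                      rev_primer = character(), start = integer(),
                      end = integer(), length = integer(), event = integer(),
                      footprint = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Virtual restriction digest with probe hybridisation
#'
#' Cuts each template at every unmethylated occurrence of the recognition
#' sequence (cut after `cut_offset` bases, 1 for SalI's G^TCGAC) and reports
#' every fragment with its probe-hybridisation count: the number of
#' non-overlapping local matches to the probe of >= `min_match` bp at
#' >= `min_identity`% identity (a stringent-wash approximation). Fragments
#' with a count >= 1 are the bands on the blot; identical sizes add up to
#' band intensity (multiplicity).
#'
#' @param templates A chromatid/record or list of them (e.g. the two homologs
#'   of a diploid).
#' @param enzyme_recognition_seq Recognition site (>= 4 bp; default SalI).
#' @param probe_seq Probe sequence (>= 50 bp).
#' @param respect_methylation If `TRUE`, sites covered by a
#'   `methylation_mark` feature do not cut.
#' @param cut_offset Cut position within the site.
#' @param min_match,min_identity Probe match thresholds.
#' @return data.frame: `template`, `frag_start`, `frag_end`, `length`,
#'   `probe_hits`.
#' @export
virtual_southern <- function(templates, enzyme_recognition_seq = "GTCGAC",
                             probe_seq, respect_methylation = TRUE,
                             cut_offset = 1L, min_match = 50L,
                             min_identity = 85) {
  if (nchar(enzyme_recognition_seq) < 4L) {
    stop("recognition site must be >= 4 bp", call. = FALSE)
  }
  if (nchar(probe_seq) < 50L) stop("probe must be >= 50 bp", call. = FALSE)
  if (inherits(templates, c("seq_record", "chromatid_model")) ||
      is.character(templates)) {
    templates <- list(templates)
  }
  out <- NULL
  for (tm in templates) {
    g <- .genome_seq_id(tm)
    n <- nchar(g$seq)
    m <- Biostrings::matchPattern(enzyme_recognition_seq,
                                  Biostrings::DNAString(g$seq))
    site_starts <- BiocGenerics::start(m) - 1L
    if (respect_methylation && inherits(tm, "chromatid_model")) {
      fe <- tm$features
      marks <- fe[fe$kind == "methylation_mark", , drop = FALSE]
      if (nrow(marks)) {
        blocked <- vapply(site_starts, function(s) {
          any(marks$start <= s & marks$end >= s + nchar(enzyme_recognition_seq))
        }, logical(1))
        site_starts <- site_starts[!blocked]
      }
    }
    cuts <- sort(unique(site_starts + cut_offset))
    bounds <- c(0L, cuts, n)
    for (i in seq_len(length(bounds) - 1L)) {
      fs <- bounds[i]; fe_ <- bounds[i + 1L]
      if (fe_ <= fs) next
      frag <- .substr0(g$seq, fs, fe_)
      hits <- .count_probe_hits(frag, probe_seq, min_match, min_identity)
      out <- rbind(out, data.frame(template = g$id, frag_start = fs,
                                   frag_end = fe_, length = fe_ - fs,
                                   probe_hits = hits,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Count non-overlapping probe matches >= min_match bp at >= min_identity %,
# by repeated local alignment with masking.
.count_probe_hits <- function(frag, probe, min_match, min_identity) {
  if (nchar(frag) < min_match) return(0L)
  count <- 0L
  mat <- .nuc_matrix()
  for (iter in 1:10) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(probe), Biostrings::DNAString(frag),
      type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    w <- Biostrings::nchar(aln)
    if (length(w) == 0L || w < min_match) break
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ident <- 100 * sum(pa == sa & pa != "-" & pa != "N") / length(pa)
    if (ident < min_identity) break
    count <- count + 1L
    s0 <- BiocGenerics::start(Biostrings::subject(aln))
    e0 <- BiocGenerics::end(Biostrings::subject(aln))
    mask <- paste(rep("N", e0 - s0 + 1L), collapse = "")
    substr(frag, s0, e0) <- mask
  }
  count
}

#' Band summary of a virtual Southern
#'
#' Collapses a [virtual_southern()] fragment table to the hybridising bands:
#' one row per fragment size with its multiplicity (relative intensity).
#'
#' @param digest Output of [virtual_southern()].
#' @param per_template Aggregate within templates (`TRUE`) or across all.
#' @return data.frame with `template` (optional), `length`, `multiplicity`.
#' @export
southern_bands <- function(digest, per_template = TRUE) {
  hyb <- digest[digest$probe_hits >= 1L, , drop = FALSE]
  if (!nrow(hyb)) {
    return(data.frame(template = character(), length = integer(),
                      multiplicity = integer(), stringsAsFactors = FALSE))
  }
  keyvars <- if (per_template) c("template", "length") else "length"
  agg <- stats::aggregate(list(multiplicity = hyb$length),
                          by = hyb[keyvars], FUN = length)
  agg[order(agg$length, decreasing = TRUE), , drop = FALSE]
}

#' Paralog copy ratio across a diploid model
#'
#' Counts occurrences of two named marker features (e.g. the p2 and p1 gene
#' labels) across the supplied allele models and returns the pair of counts —
#' the in-silico analogue of semi-quantitative paralog PCR for sizing a
#' duplication.
#'
#' @param allele_models List of [chromatid_model()] (both homologs).
#' @param marker_a,marker_b Feature names to count.
#' @return Named integer vector `c(<marker_a> = count, <marker_b> = count)`.
#' @export
copy_ratio <- function(allele_models, marker_a = "p2", marker_b = "p1") {
  if (inherits(allele_models, "chromatid_model")) {
    allele_models <- list(allele_models)
  }
  count_marker <- function(marker) {
    sum(vapply(allele_models, function(m) {
      sum(m$features$name == marker)
    }, integer(1)))
  }
  a <- count_marker(marker_a)
  b <- count_marker(marker_b)
  if (a == 0L && b == 0L) {
    stop("markers absent from all models", call. = FALSE)
  }
  stats::setNames(c(a, b), c(marker_a, marker_b))
}
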