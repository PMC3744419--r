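# Reversed-ends transposition (RET) and standard transposition on chromatids.
#
# Geometry used throughout: the element contributing the 3' terminus lies to
# the LEFT of the element contributing the 5' terminus, with the two termini
# facing each other across the inter-element segment (the configuration that
# makes the terminus pair look like a single transposon to the transposase).
# cut3 = right edge of the 3' terminus, cut5 = left edge of the 5' terminus.

# Map features through a piecewise copy of the source sequence.
# pieces: list of list(src_start, src_end, offset); a feature is carried into
# every piece that fully contains it (features in overlapping source pieces
# are duplicated, which is exactly what a tandem duplication does).
.remap_features <- function(fe, pieces) {
  out <- fe[0, , drop = FALSE]
  for (p in pieces) {
    keep <- fe$start >= p$src_start & fe$end <= p$src_end &
      !(fe$start == fe$end & fe$start == p$src_end)
    if (any(keep)) {
      sub <- fe[keep, , drop = FALSE]
      sub$start <- sub$start + p$offset
      sub$end <- sub$end + p$offset
      out <- rbind(out, sub)
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insert a transposon at a target site (standard cut-and-paste)
#'
#' Implements the canonical insertion with target site duplication: the
#' `tsd_len`-bp target appears once on each side of the inserted element.
#' The result is `[0, pos+tsd)` + element + target + `[pos+tsd, N)`.
#'
#' @param chromatid A [chromatid_model()].
#' @param te A [transposon_def()].
#' @param target A [target_site()] on `chromatid` (its `tsd_len` governs the
#'   duplication length; use `tsd_len = 0` for footprint-free insertion).
#' @param orientation `"+"` (consensus orientation) or `"-"`.
#' @return A new [chromatid_model()] with `te_instance`, `te_terminus` and
#'   `target_site` features added and downstream features shifted.
#' @export
insert_element <- function(chromatid, te, target, orientation = "+") {
  seq <- chromatid$record$sequence
  n <- nchar(seq)
  pos <- target$pos
  tsd <- target$tsd_len
  if (pos < 0L || pos + tsd > n) stop("target out of bounds", call. = FALSE)
  fe <- chromatid$features
  tes <- fe[fe$kind == "te_instance", , drop = FALSE]
  if (nrow(tes) && any(pos < tes$end & pos + tsd > tes$start)) {
    stop("target overlaps an existing te_instance", call. = FALSE)
  }
  te_seq <- if (orientation == "+") te$sequence else reverse_complement(te$sequence)
  L <- nchar(te_seq)
  shift <- L + tsd
  ins_at <- pos + tsd
  new_seq <- paste0(.substr0(seq, 0L, ins_at), te_seq, target$seq,
                    .substr0(seq, ins_at, n))

  fe2 <- fe
  span <- fe2$start < ins_at & fe2$end > ins_at
  fe2$end[span] <- fe2$end[span] + shift
  after <- fe2$start >= ins_at
  fe2$start[after] <- fe2$start[after] + shift
  fe2$end[after] <- fe2$end[after] + shift

  te_start <- ins_at
  te_end <- ins_at + L
  if (orientation == "+") {
    t5 <- c(te_start, te_start + te$tir5_len)
    t3 <- c(te_end - te$tir3_len, te_end)
  } else {
    t3 <- c(te_start, te_start + te$tir3_len)
    t5 <- c(te_end - te$tir5_len, te_end)
  }
  add <- rbind(
    .feat(te_start, te_end, "te_instance", te$name, strand = orientation,
          attrs = .attrs_make(te = te$name, family = te$family, tsd = target$seq,
                              tsd_len = tsd, has_tsd_pair = 1L),
          chrom = chromatid$record$id),
    .feat(t5[1], t5[2], "te_terminus", paste0(te$name, "_5prime"),
          strand = orientation,
          attrs = .attrs_make(terminus = "5prime", te = te$name),
          chrom = chromatid$record$id),
    .feat(t3[1], t3[2], "te_terminus", paste0(te$name, "_3prime"),
          strand = orientation,
          attrs = .attrs_make(terminus = "3prime", te = te$name),
          chrom = chromatid$record$id)
  )
  if (tsd > 0L) {
    add <- rbind(add,
                 .feat(pos, pos + tsd, "target_site", "tsd_left",
                       attrs = .attrs_make(tsd = target$seq),
                       chrom = chromatid$record$id),
                 .feat(te_end, te_end + tsd, "target_site", "tsd_right",
                       attrs = .attrs_make(tsd = target$seq),
                       chrom = chromatid$record$id))
  }
  cen <- chromatid$centromere_pos
  if (cen >= ins_at) cen <- cen + shift
  chromatid_model(seq_record(chromatid$record$id, new_seq,
                             chromatid$record$description),
                  rbind(fe2, add), centromere_pos = cen)
}

#' Excise a transposon, leaving a footprint
#'
#' Removes a `te_instance` and rejoins the flanks. For an element inserted by
#' [insert_element()] (which records its flanking TSD pair) the two TSD copies
#' collapse back to one; for a one-sided junction element only the element
#' itself is removed. The rejoined junction then receives a footprint drawn
#' from `footprint_model`: with equal probability 1 or 2 base substitutions or
#' deletions (the common Ac/Ds excision scars), or nothing for `"perfect"`.
#'
#' @param chromatid A [chromatid_model()].
#' @param te_instance Name of the `te_instance` feature to excise (or its row
#'   of the feature table).
#' @param footprint_model `"default"` or `"perfect"`.
#' @param seed Integer seed (mandatory for the stochastic default model).
#' @param which When several instances share the name, the one to excise
#'   (genome order).
#' @return List with `chromatid` (post-excision model) and `footprint`
#'   (character description, e.g. `"del2"`, `""` for perfect).
#' @export
excise_element <- function(chromatid, te_instance,
                           footprint_model = c("default", "perfect"),
                           seed = NULL, which = 1L) {
  footprint_model <- match.arg(footprint_model)
  fe <- chromatid$features
  if (is.character(te_instance)) {
    idx <- base::which(fe$kind == "te_instance" & fe$name == te_instance)
    if (!length(idx)) stop("no te_instance named ", te_instance, call. = FALSE)
    if (which > length(idx)) stop("fewer than ", which, " instances named ",
                                  te_instance, call. = FALSE)
    row <- fe[idx[which], ]
  } else {
    row <- te_instance
  }
  term <- fe[fe$kind == "te_terminus" & fe$start >= row$start &
               fe$end <= row$end, , drop = FALSE]
  if (!nrow(term)) {
    stop("te_instance lacks terminus annotations", call. = FALSE)
  }
  tsd_len <- suppressWarnings(as.integer(.attrs_get(row$attrs, "tsd_len")))
  paired <- identical(.attrs_get(row$attrs, "has_tsd_pair"), "1")
  rem_start <- row$start
  rem_end <- if (paired && !is.na(tsd_len)) row$end + tsd_len else row$end
  seq <- chromatid$record$sequence
  n <- nchar(seq)
  new_seq <- paste0(.substr0(seq, 0L, rem_start), .substr0(seq, rem_end, n))
  j <- rem_start  # junction position in the new sequence

  fp <- ""
  ndel <- 0L
  if (footprint_model == "default") {
    if (is.null(seed)) stop("seed required for the default footprint model",
                            call. = FALSE)
    edits <- withr::with_seed(seed, {
      kind <- sample(c("sub1", "sub2", "del1", "del2"), 1L)
      nb <- as.integer(substr(kind, 4L, 4L))
      reps <- sample(c("A", "C", "G", "T"), nb, replace = TRUE)
      list(kind = kind, nb = nb, reps = reps)
    })
    fp <- edits$kind
    if (startsWith(edits$kind, "sub")) {
      for (i in seq_len(edits$nb)) {
        p <- j - i  # 0-based position of the base to substitute
        if (p < 0L) next
        old <- .substr0(new_seq, p, p + 1L)
        new <- edits$reps[i]
        if (new == old) new <- setdiff(c("A", "C", "G", "T"), old)[1]
        substr(new_seq, p + 1L, p + 1L) <- new
      }
    } else {
      ndel <- min(edits$nb, j)
      new_seq <- paste0(.substr0(new_seq, 0L, j - ndel),
                        .substr0(new_seq, j, nchar(new_seq)))
    }
  }

  rem_len <- rem_end - rem_start
  keep <- !(fe$start < rem_end & fe$end > rem_start) |
    (fe$start == fe$end & (fe$start <= rem_start | fe$start >= rem_end))
  fe2 <- fe[keep, , drop = FALSE]
  after <- fe2$start >= rem_end
  fe2$start[after] <- fe2$start[after] - rem_len
  fe2$end[after] <- fe2$end[after] - rem_len
  if (ndel > 0L) {
    aj <- fe2$start >= j
    fe2$start[aj] <- fe2$start[aj] - ndel
    fe2$end[fe2$end >= j] <- fe2$end[fe2$end >= j] - ndel
  }
  cen <- chromatid$centromere_pos
  if (cen >= rem_end) cen <- cen - rem_len - ndel
  out <- chromatid_model(seq_record(chromatid$record$id, new_seq,
                                    chromatid$record$description),
                         fe2, centromere_pos = cen)
  list(chromatid = out, footprint = fp)
}

#' Specify a reversed-ends transposition event
#'
#' Names the two donor termini (a 3' terminus and a 5' terminus facing each
#' other across the inter-element segment) and the insertion target on the
#' sister chromatid.
#'
#' @param donor_3prime,donor_5prime Names of `te_terminus` features on the
#'   progenitor (or single feature rows).
#' @param target A [target_site()].
#' @param join_mode `"duplication_deletion"` (the duplication-forming
#'   resolution) or `"dicentric"` (the bridge-forming alternative).
#' @return Object of class `ret_event_spec`.
#' @export
ret_event_spec <- function(donor_3prime, donor_5prime, target,
                           join_mode = c("duplication_deletion", "dicentric")) {
  join_mode <- match.arg(join_mode)
  structure(list(donor_3prime = donor_3prime, donor_5prime = donor_5prime,
                 target = target, join_mode = join_mode),
            class = "ret_event_spec")
}

.find_terminus <- function(chromatid, ref, which) {
  fe <- chromatid$features
  if (is.character(ref)) {
    idx <- which(fe$kind == "te_terminus" & fe$name == ref)
    if (!length(idx)) stop("no te_terminus named ", ref, call. = FALSE)
    f <- fe[idx[1], ]
  } else {
    f <- ref
  }
  got <- .attrs_get(f$attrs, "terminus")
  if (!is.na(got) && !identical(got, which)) {
    stop(sprintf("terminus '%s' is %s, expected %s", f$name, got, which),
         call. = FALSE)
  }
  f
}

# The te_instance containing a terminus feature (may be absent for bare toys).
.enclosing_te <- function(chromatid, term) {
  fe <- chromatid$features
  hit <- fe$kind == "te_instance" & fe$start <= term$start & fe$end >= term$end
  if (any(hit)) fe[which(hit)[1], ] else term
}

#' Simulate reversed-ends transposition on sister chromatids
#'
#' Models the RET reaction of a pair of reversely-oriented transposon termini:
#' the transposase cuts one chromatid at the 3' terminus of the left element
#' and the 5' terminus of the right element, circularises the inter-element
#' segment, and inserts the freed termini into a target site on the (identical)
#' sister chromatid. The duplication-forming resolution yields one chromatid
#' carrying a tandem direct duplication and one carrying the reciprocal
#' deletion, each junction bearing one copy of the target-site sequence.
#' Sequence is conserved: `len(dup) + len(del) + len(circle) = 2N + tsd_len`.
#'
#' @param progenitor A [chromatid_model()]; the sister is an identical copy.
#' @param event A [ret_event_spec()]. The target must lie outside the interval
#'   spanned by the two donor elements.
#' @return Object of class `ret_outcome`: for `join_mode =
#'   "duplication_deletion"` a list with `duplication_product`,
#'   `deletion_product` (chromatid models), `circle` (a [seq_record()]),
#'   `junctions` (data frame of junction records), `event`, `side`,
#'   and `viable = TRUE`. For `"dicentric"` the dicentric/acentric pair,
#'   flagged `viable = FALSE`.
#' @export
ret_transpose <- function(progenitor, event) {
  stopifnot(inherits(event, "ret_event_spec"))
  P <- progenitor$record$sequence
  N <- nchar(P)
  d3 <- .find_terminus(progenitor, event$donor_3prime, "3prime")
  d5 <- .find_terminus(progenitor, event$donor_5prime, "5prime")
  cut3 <- d3$end
  cut5 <- d5$start
  if (cut3 >= cut5) {
    stop("expected the 3' terminus element left of the 5' terminus element ",
         "with termini facing across the inter-element segment ",
         "(reverse-complement the chromatid for the mirrored configuration)",
         call. = FALSE)
  }
  e3 <- .enclosing_te(progenitor, d3)
  e5 <- .enclosing_te(progenitor, d5)
  pair_start <- min(e3$start, e5$start)
  pair_end <- max(e3$end, e5$end)
  tg <- event$target
  tp <- tg$pos
  tsd <- tg$tsd_len
  if (!identical(tg$seq, .substr0(P, tp, tp + tsd))) {
    stop("target site sequence does not match the progenitor", call. = FALSE)
  }
  if (tp + tsd > pair_start && tp < pair_end) {
    stop("target lies inside the transposon pair interval", call. = FALSE)
  }
  target_right <- tp >= pair_end
  mid <- (pair_start + pair_end) / 2
  side <- if (sign(tp - mid) == sign(progenitor$centromere_pos - mid)) {
    "proximal"
  } else "distal"

  id <- progenitor$record$id
  circle <- seq_record(paste0(id, "_circle"), .substr0(P, cut3, cut5),
                       "excised inter-element circle")

  if (event$join_mode == "dicentric") {
    # Bridge-forming resolution: classify only, do not propagate.
    dic <- seq_record(paste0(id, "_dicentric"),
                      paste0(reverse_complement(.substr0(P, cut5, N)),
                             .substr0(P, tp, N)),
                      "dicentric product (non-viable)")
    ace <- seq_record(paste0(id, "_acentric"),
                      paste0(.substr0(P, 0L, tp + tsd),
                             reverse_complement(.substr0(P, 0L, cut3))),
                      "acentric product (non-viable)")
    return(structure(list(dicentric = dic, acentric = ace, circle = circle,
                          event = event, side = side, viable = FALSE),
                     class = "ret_outcome"))
  }

  fe <- progenitor$features
  te3_name <- if (!is.na(.attrs_get(d3$attrs, "te"))) .attrs_get(d3$attrs, "te") else d3$name
  te5_name <- if (!is.na(.attrs_get(d5$attrs, "te"))) .attrs_get(d5$attrs, "te") else d5$name

  if (target_right) {
    dup_seq <- paste0(.substr0(P, 0L, tp + tsd), .substr0(P, cut5, N))
    del_seq <- paste0(.substr0(P, 0L, cut3), .substr0(P, tp, N))
    dup_pieces <- list(list(src_start = 0L, src_end = tp + tsd, offset = 0L),
                       list(src_start = cut5, src_end = N,
                            offset = tp + tsd - cut5))
    del_pieces <- list(list(src_start = 0L, src_end = cut3, offset = 0L),
                       list(src_start = tp, src_end = N, offset = cut3 - tp))
    dup_junc <- data.frame(product = "duplication",
                           left_flank_10bp = .substr0(dup_seq, max(0L, tp - 10L), tp),
                           tsd = .substr0(dup_seq, tp, tp + tsd),
                           te_terminus = "5prime", te_name = te5_name,
                           coordinate = tp + tsd, stringsAsFactors = FALSE)
    del_junc <- data.frame(product = "deletion",
                           left_flank_10bp = .substr0(del_seq, max(0L, cut3 - 10L), cut3),
                           tsd = .substr0(del_seq, cut3, cut3 + tsd),
                           te_terminus = "3prime", te_name = te3_name,
                           coordinate = cut3, stringsAsFactors = FALSE)
  } else {
    dup_seq <- paste0(.substr0(P, 0L, cut3), .substr0(P, tp, N))
    del_seq <- paste0(.substr0(P, 0L, tp + tsd), .substr0(P, cut5, N))
    dup_pieces <- list(list(src_start = 0L, src_end = cut3, offset = 0L),
                       list(src_start = tp, src_end = N, offset = cut3 - tp))
    del_pieces <- list(list(src_start = 0L, src_end = tp + tsd, offset = 0L),
                       list(src_start = cut5, src_end = N,
                            offset = tp + tsd - cut5))
    dup_junc <- data.frame(product = "duplication",
                           left_flank_10bp = .substr0(dup_seq, max(0L, cut3 - 10L), cut3),
                           tsd = .substr0(dup_seq, cut3, cut3 + tsd),
                           te_terminus = "3prime", te_name = te3_name,
                           coordinate = cut3, stringsAsFactors = FALSE)
    del_junc <- data.frame(product = "deletion",
                           left_flank_10bp = .substr0(del_seq, max(0L, tp - 10L), tp),
                           tsd = .substr0(del_seq, tp, tp + tsd),
                           te_terminus = "5prime", te_name = te5_name,
                           coordinate = tp + tsd, stringsAsFactors = FALSE)
  }

  dup_fe <- .remap_features(fe, dup_pieces)
  del_fe <- .remap_features(fe, del_pieces)
  dup_cen <- .map_point(progenitor$centromere_pos, dup_pieces)
  del_cen <- .map_point(progenitor$centromere_pos, del_pieces)

  dup <- chromatid_model(seq_record(paste0(id, "_dup"), dup_seq,
                                    "tandem direct duplication product"),
                         dup_fe, centromere_pos = dup_cen)
  del <- chromatid_model(seq_record(paste0(id, "_del"), del_seq,
                                    "reciprocal deletion product"),
                         del_fe, centromere_pos = del_cen)
  structure(list(duplication_product = dup, deletion_product = del,
                 circle = circle, junctions = rbind(dup_junc, del_junc),
                 event = event, side = side, viable = TRUE),
            class = "ret_outcome")
}

# Map a single point through remap pieces (first containing piece wins).
.map_point <- function(pos, pieces) {
  for (p in pieces) {
    if (pos >= p$src_start && pos <= p$src_end) return(pos + p$offset)
  }
  NA_integer_
}

#' @export
print.ret_outcome <- function(x, ...) {
  if (isTRUE(x$viable)) {
    cat(sprintf("<ret_outcome> %s target: dup %d bp, del %d bp, circle %d bp\n",
                x$side, nchar(x$duplication_product$record$sequence),
                nchar(x$deletion_product$record$sequence),
                nchar(x$circle$sequence)))
  } else {
    cat("<ret_outcome> dicentric/acentric pair (non-viable)\n")
  }
  invisible(x)
}

#' Locate the element at a duplication junction
#'
#' Finds the `te_instance` feature lying between an upstream and a downstream
#' primer anchor — on a duplication product this is the element spanning the
#' repeat junction (the one whose excision brings the two primers into
#' amplifiable range).
#'
#' @param chromatid A [chromatid_model()].
#' @param upstream,downstream Names of the flanking primer features.
#' @param window Maximum distance (bp) from primer to element edge.
#' @return The matching feature row (errors if none or several match).
#' @export
find_junction_te <- function(chromatid, upstream = "primer1",
                             downstream = "primer3", window = 2000L) {
  fe <- chromatid$features
  tes <- fe[fe$kind == "te_instance", , drop = FALSE]
  up <- fe[fe$kind == "primer" & fe$name == upstream, , drop = FALSE]
  dn <- fe[fe$kind == "primer" & fe$name == downstream, , drop = FALSE]
  hit <- vapply(seq_len(nrow(tes)), function(i) {
    any(up$end <= tes$start[i] & up$end >= tes$start[i] - window) &&
      any(dn$start >= tes$end[i] & dn$start <= tes$end[i] + window)
  }, logical(1))
  if (sum(hit) != 1L) {
    stop("expected exactly one junction element, found ", sum(hit),
         call. = FALSE)
  }
  tes[hit, , drop = FALSE]
}

#' Write RET products to disk
#'
#' Emits product FASTA files, companion GFF3 feature files, and a JSON
#' event/junction log sufficient to reproduce and check the event.
#'
#' @param outcome A `ret_outcome` from [ret_transpose()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_ret_products <- function(outcome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(outcome$viable)) {
    write_fasta(outcome$duplication_product, file.path(dir, "duplication.fa"))
    write_fasta(outcome$deletion_product, file.path(dir, "deletion.fa"))
    write_features_gff3(outcome$duplication_product$features,
                        file.path(dir, "duplication.gff3"))
    write_features_gff3(outcome$deletion_product$features,
                        file.path(dir, "deletion.gff3"))
  } else {
    write_fasta(list(outcome$dicentric, outcome$acentric),
                file.path(dir, "nonviable.fa"))
  }
  write_fasta(outcome$circle, file.path(dir, "circle.fa"))
  log <- list(side = outcome$side,
              join_mode = outcome$event$join_mode,
              viable = outcome$viable,
              target = unclass(outcome$event$target),
              junctions = if (!is.null(outcome$junctions)) outcome$junctions)
  jsonlite::write_json(log, file.path(dir, "event.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
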