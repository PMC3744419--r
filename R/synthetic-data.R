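# Synthetic genomes with planted events and a machine-readable truth
# manifest: ordinary TE insertions, RET-signature tandem duplications, NAHR
# three-copy decoys, and junctions whose element excised leaving a footprint.
# This is the acceptance surface for the scanner.

.with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Random background sequence
#'
#' i.i.d. bases at the stated GC fraction; deterministic under `seed`.
#' The default background carries no repeat families, so scanner hits on a
#' benchmark genome come only from planted events.
#'
#' @param length Sequence length (> 0).
#' @param gc_fraction GC fraction in `[0, 1]`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param id Record id.
#' @return A [seq_record()].
#' @export
random_background <- function(length, gc_fraction = 0.47, seed = NULL,
                              id = "synthetic") {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  .with_opt_seed(seed, seq_record(id, .random_dna(length, gc_fraction),
                                  "i.i.d. background"))
}

# Mutate a sequence with exactly n substitutions at distinct positions.
.mutate_subs <- function(seq, n_sub) {
  if (n_sub <= 0L) return(seq)
  n <- nchar(seq)
  stopifnot(n_sub <= n)
  pos <- sample.int(n, n_sub)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Draw a TSD different from t1 in at least one position.
.draw_other_tsd <- function(t1) {
  repeat {
    t2 <- .random_dna(nchar(t1), 0.5)
    if (t2 != t1) return(t2)
  }
}

.genome_seq_id <- function(genome) {
  if (inherits(genome, "chromatid_model")) {
    list(seq = genome$record$sequence, id = genome$record$id)
  } else if (inherits(genome, "seq_record")) {
    list(seq = genome$sequence, id = genome$id)
  } else list(seq = genome, id = "seq")
}

.splice <- function(seq, at, insert) {
  paste0(.substr0(seq, 0L, at), insert, .substr0(seq, at, nchar(seq)))
}

.rewrap <- function(genome, new_seq) {
  g <- .genome_seq_id(genome)
  seq_record(g$id, new_seq, "synthetic genome with planted events")
}

#' Plant an ordinary TE insertion
#'
#' Standard cut-and-paste insertion with a two-sided TSD taken from the
#' genome at `pos`. Not a duplication: the scanner should find one intact hit
#' and make no call.
#'
#' @param genome Sequence carrier.
#' @param te [transposon_def()].
#' @param pos 0-based target position.
#' @param seed Unused (the insertion is deterministic); kept for a uniform
#'   planting interface.
#' @return List with `genome` (new [seq_record()]) and `entry` (manifest
#'   entry).
#' @export
plant_te_insertion <- function(genome, te, pos, seed = NULL) {
  g <- .genome_seq_id(genome)
  tl <- te$tsd_len
  t1 <- .substr0(g$seq, pos, pos + tl)
  L <- nchar(te$sequence)
  new_seq <- .splice(g$seq, pos + tl, paste0(te$sequence, t1))
  entry <- list(event_type = "te_insertion", te_name = te$name,
                coordinates = list(te1_start = pos + tl, te1_end = pos + tl + L),
                unit_length = NA, copy_divergence = NA,
                tsd_seqs = list(t1 = t1),
                expected_call = "none")
  list(genome = .rewrap(genome, new_seq), entry = entry)
}

#' Plant an RET-signature tandem direct duplication
#'
#' Builds the sequence structure an RET event leaves behind. Default
#' (element-leading) layout, with `t1` read from the genome at `pos` and
#' `t2` a different random TSD:
#' `t1 TE t1 U1 t2 TE t1 U2 t2` — the first element carries the matched TSD
#' pair of the original insertion, the second carries `t1` on exactly one
#' side, and the repeat copies are `t1·U·t2` (length `unit_length`, TSDs
#' included). `U2` is `U1` mutated to `copy_divergence` (substitutions only).
#' With `fractured`, both element copies are the given terminal fragment and
#' the mirrored element-trailing layout (the distal-target mechanism) is
#' produced instead.
#'
#' @param genome Sequence carrier.
#' @param te [transposon_def()].
#' @param pos 0-based plant position.
#' @param unit_length Repeat-unit length in bp, TSDs included (>= 20).
#' @param copy_divergence Fraction of substituted sites between the two
#'   repeat copies, in `[0, 0.2]`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param fractured Optional list `list(end = "3prime", length = n)` planting
#'   terminal fragments instead of complete elements.
#' @return List with `genome` and `entry`.
#' @export
plant_ret_duplication <- function(genome, te, pos, unit_length,
                                  copy_divergence = 0, seed = NULL,
                                  fractured = NULL) {
  stopifnot(unit_length >= 20L)
  if (copy_divergence < 0 || copy_divergence > 0.2) {
    stop("copy_divergence must be in [0, 0.2]", call. = FALSE)
  }
  g <- .genome_seq_id(genome)
  tl <- te$tsd_len
  core_len <- unit_length - 2L * tl
  stopifnot(core_len >= 1L)
  .with_opt_seed(seed, {
    t1 <- .substr0(g$seq, pos, pos + tl)
    t2 <- .draw_other_tsd(t1)
    core1 <- .random_dna(core_len, 0.5)
    n_sub <- min(core_len, round(copy_divergence * unit_length))
    core2 <- .mutate_subs(core1, n_sub)
    if (is.null(fractured)) {
      el <- te$sequence
      L <- nchar(el)
      cassette <- paste0(el, t1, core1, t2, el, t1, core2, t2)
      new_seq <- .splice(g$seq, pos + tl, cassette)
      te1_start <- pos + tl
      te2_start <- te1_start + L + unit_length
      coords <- list(te1_start = te1_start, te1_end = te1_start + L,
                     te2_start = te2_start, te2_end = te2_start + L,
                     repeat1_start = te1_start + L, repeat1_end = te2_start,
                     repeat2_start = te2_start + L,
                     repeat2_end = te2_start + L + unit_length)
    } else {
      L0 <- nchar(te$sequence)
      fl <- as.integer(fractured$length)
      el <- if (identical(fractured$end, "5prime")) {
        .substr0(te$sequence, 0L, fl)
      } else {
        .substr0(te$sequence, L0 - fl, L0)
      }
      L <- nchar(el)
      # element-trailing (distal-mechanism) layout, inserted before the
      # genomic t1 at pos: [t2 U1 t1 F][t2 U2 t1 F] t1
      cassette <- paste0(t2, core1, t1, el, t2, core2, t1, el)
      new_seq <- .splice(g$seq, pos, cassette)
      te1_start <- pos + unit_length
      te2_start <- te1_start + L + unit_length
      coords <- list(te1_start = te1_start, te1_end = te1_start + L,
                     te2_start = te2_start, te2_end = te2_start + L,
                     repeat1_start = pos, repeat1_end = te1_start,
                     repeat2_start = te1_start + L, repeat2_end = te2_start)
    }
    entry <- list(event_type = "ret_duplication", te_name = te$name,
                  coordinates = coords, unit_length = unit_length,
                  copy_divergence = copy_divergence,
                  tsd_seqs = list(t1 = t1, t2 = t2),
                  fractured = if (is.null(fractured)) NULL else fractured,
                  expected_call = "ret_consistent")
    list(genome = .rewrap(genome, new_seq), entry = entry)
  })
}

#' Plant an NAHR-like three-copy decoy
#'
#' `t TE t U t TE t U t TE t`: the recurrent-recombination structure with a
#' third element copy and matched two-sided TSDs on every copy. The scanner
#' should report it but never class it RET-consistent.
#'
#' @inheritParams plant_ret_duplication
#' @return List with `genome` and `entry` (`expected_call = "nahr_like"`).
#' @export
plant_nahr_decoy <- function(genome, te, pos, unit_length, seed = NULL) {
  stopifnot(unit_length >= 20L)
  g <- .genome_seq_id(genome)
  tl <- te$tsd_len
  core_len <- unit_length - 2L * tl
  stopifnot(core_len >= 1L)
  .with_opt_seed(seed, {
    t1 <- .substr0(g$seq, pos, pos + tl)
    core <- .random_dna(core_len, 0.5)
    el <- te$sequence
    L <- nchar(el)
    unit <- paste0(t1, core, t1)
    cassette <- paste0(el, unit, el, unit, el, t1)
    new_seq <- .splice(g$seq, pos + tl, cassette)
    te1_start <- pos + tl
    te2_start <- te1_start + L + unit_length
    te3_start <- te2_start + L + unit_length
    entry <- list(event_type = "nahr_decoy", te_name = te$name,
                  coordinates = list(te1_start = te1_start,
                                     te1_end = te1_start + L,
                                     te2_start = te2_start,
                                     te2_end = te2_start + L,
                                     te3_start = te3_start,
                                     te3_end = te3_start + L,
                                     repeat1_start = te1_start + L,
                                     repeat1_end = te2_start,
                                     repeat2_start = te2_start + L,
                                     repeat2_end = te3_start),
                  unit_length = unit_length, copy_divergence = 0,
                  tsd_seqs = list(t1 = t1),
                  expected_call = "nahr_like")
    list(genome = .rewrap(genome, new_seq), entry = entry)
  })
}

#' Plant an RET duplication whose junction element excised
#'
#' The element-leading RET structure with the middle (junction) element
#' replaced by a 1-2 bp excision footprint: `t1 TE t1 U1 t2 <fp> t1 U2 t2`.
#' The repeat copies remain nearly identical, but with only one element copy
#' the search criteria produce no call — the documented blind spot.
#'
#' @inheritParams plant_ret_duplication
#' @return List with `genome` and `entry` (`expected_call = "none"`).
#' @export
plant_excised_junction <- function(genome, te, pos, unit_length, seed = NULL) {
  stopifnot(unit_length >= 20L)
  g <- .genome_seq_id(genome)
  tl <- te$tsd_len
  core_len <- unit_length - 2L * tl
  stopifnot(core_len >= 3L)
  .with_opt_seed(seed, {
    t1 <- .substr0(g$seq, pos, pos + tl)
    t2 <- .draw_other_tsd(t1)
    core1 <- .random_dna(core_len, 0.5)
    core2 <- .mutate_subs(core1, min(core_len, round(0.02 * unit_length)))
    el <- te$sequence
    L <- nchar(el)
    # footprint at the t2|t1 junction where the element used to sit
    kind <- sample(c("sub1", "sub2", "del1", "del2"), 1L)
    nb <- as.integer(substr(kind, 4L, 4L))
    t2fp <- t2
    if (startsWith(kind, "sub")) {
      for (i in seq_len(nb)) {
        p <- nchar(t2fp) - i + 1L
        old <- substr(t2fp, p, p)
        substr(t2fp, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    } else {
      t2fp <- substr(t2fp, 1L, nchar(t2fp) - nb)
    }
    cassette <- paste0(el, t1, core1, t2fp, t1, core2, t2)
    new_seq <- .splice(g$seq, pos + tl, cassette)
    te1_start <- pos + tl
    entry <- list(event_type = "excised_junction", te_name = te$name,
                  coordinates = list(te1_start = te1_start,
                                     te1_end = te1_start + L,
                                     repeat1_start = te1_start + L,
                                     repeat1_end = te1_start + L +
                                       nchar(t1) + core_len + nchar(t2fp)),
                  unit_length = unit_length, copy_divergence = 0.02,
                  tsd_seqs = list(t1 = t1, t2 = t2),
                  footprint = kind,
                  expected_call = "none")
    list(genome = .rewrap(genome, new_seq), entry = entry)
  })
}

#' Built-in synthetic TE library for benchmarks
#'
#' Three deterministic hAT-like consensi (568, 904 and 1500 bp — the first
#' two sized like the dhAT elements the scan archetypes involve) with 11 bp
#' terminal inverted repeats and 8 bp TSDs. Each element is its own family.
#'
#' @return Named list of [transposon_def()].
#' @export
benchmark_te_library <- function() {
  withr::with_seed(.FIXTURE_MASTER_SEED + 2L, {
    lens <- c(synthAT568 = 568L, synthAT904 = 904L, synthAT1500 = 1500L)
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

#' Benchmark configuration
#'
#' Event counts and parameter ranges for [generate_benchmark()]. Defaults:
#' 2 Mb genome at GC 0.47 carrying 20 RET duplications, 5 NAHR decoys, 5
#' excised junctions and 10 plain insertions, with repeat units of
#' 100-2000 bp and copy divergence 0-5%.
#'
#' @param ... Named overrides; unknown names are an error.
#' @return Named list.
#' @export
benchmark_config <- function(...) {
  cfg <- list(genome_length = 2000000L, gc = 0.47,
              n_ret = 20L, n_nahr = 5L, n_excised = 5L, n_insertions = 10L,
              unit_min = 100L, unit_max = 2000L,
              div_min = 0, div_max = 0.05,
              margin = 2000L)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown benchmark config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Generate a benchmark genome with truth manifest
#'
#' Places the configured events at seeded, non-overlapping positions (one
#' event per equal-width slot) on an i.i.d. background and records exact
#' ground truth for each: planted coordinates, TSDs, divergence and the call
#' the scanner is expected to make. Identical `(config, seed)` give
#' byte-identical output.
#'
#' @param config [benchmark_config()].
#' @param seed Integer seed.
#' @param te_library TE library to draw elements from (default
#'   [benchmark_te_library()]).
#' @return List of class `ret_benchmark`: `genome` (a [seq_record()]),
#'   `manifest` (genome id, seed, config, list of event entries),
#'   `te_library`.
#' @export
generate_benchmark <- function(config = benchmark_config(), seed = 1L,
                               te_library = benchmark_te_library()) {
  n_ev <- config$n_ret + config$n_nahr + config$n_excised + config$n_insertions
  max_te <- max(vapply(te_library, function(t) nchar(t$sequence), 1L))
  max_cassette <- 3L * max_te + 2L * config$unit_max + 200L
  slot <- (config$genome_length - 2L * config$margin) %/% n_ev
  if (slot <= max_cassette + 100L) {
    stop("genome too small for the requested events", call. = FALSE)
  }
  withr::with_seed(seed, {
    genome <- random_background(config$genome_length, config$gc,
                                id = sprintf("bench_seed%d", seed))
    types <- sample(c(rep("ret_duplication", config$n_ret),
                      rep("nahr_decoy", config$n_nahr),
                      rep("excised_junction", config$n_excised),
                      rep("te_insertion", config$n_insertions)))
    events <- vector("list", n_ev)
    offset <- 0L
    for (i in seq_len(n_ev)) {
      base <- config$margin + (i - 1L) * slot
      pos0 <- base + sample.int(slot - max_cassette - 100L, 1L)
      pos <- pos0 + offset
      te <- te_library[[sample.int(length(te_library), 1L)]]
      unit <- sample(config$unit_min:config$unit_max, 1L)
      div <- stats::runif(1L, config$div_min, config$div_max)
      res <- switch(types[i],
        ret_duplication = plant_ret_duplication(genome, te, pos, unit, div),
        nahr_decoy = plant_nahr_decoy(genome, te, pos, unit),
        excised_junction = plant_excised_junction(genome, te, pos, unit),
        te_insertion = plant_te_insertion(genome, te, pos))
      inserted <- nchar(res$genome$sequence) - nchar(genome$sequence)
      offset <- offset + inserted
      genome <- res$genome
      events[[i]] <- res$entry
    }
    manifest <- list(genome_id = genome$id, seed = seed,
                     generator_params = config, events = events)
    structure(list(genome = genome, manifest = manifest,
                   te_library = te_library),
              class = "ret_benchmark")
  })
}

#' @export
print.ret_benchmark <- function(x, ...) {
  cat(sprintf("<ret_benchmark> %s: %d bp, %d planted events\n",
              x$genome$id, nchar(x$genome$sequence),
              length(x$manifest$events)))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Emits `genome.fa`, `truth.json` (the manifest) and `truth.bed` (planted
#' event intervals).
#'
#' @param bench A `ret_benchmark`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$genome, file.path(dir, "genome.fa"))
  jsonlite::write_json(bench$manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ev <- bench$manifest$events
  bed <- features(chrom = bench$genome$id,
                  start = vapply(ev, function(e) {
                    as.numeric(e$coordinates$te1_start)
                  }, numeric(1)),
                  end = vapply(ev, function(e) {
                    max(as.numeric(unlist(e$coordinates)))
                  }, numeric(1)),
                  kind = "label",
                  name = vapply(ev, function(e) e$event_type, ""))
  write_features_bed(bed, file.path(dir, "truth.bed"))
  invisible(dir)
}

#' Score a scan report against a truth manifest
#'
#' Breakpoint-exact recall of RET duplications (all four repeat coordinates
#' must match the planted truth), plus false-call accounting on decoys,
#' excised junctions and plain insertions.
#'
#' @param report `scan_report` from [scan_genome()].
#' @param manifest Truth manifest from [generate_benchmark()].
#' @return List with `n_ret`, `n_ret_exact`, `recall`, `false_ret_calls`
#'   (RET-consistent calls not matching any planted duplication),
#'   `decoy_ret_calls`, `excised_calls`, per-event details.
#' @export
score_scan <- function(report, manifest) {
  calls <- report$calls
  ret_calls <- calls[calls$tsd_class == "ret_consistent", , drop = FALSE]
  ev <- manifest$events
  ret_ev <- Filter(function(e) e$event_type == "ret_duplication", ev)
  matched_call <- rep(FALSE, nrow(ret_calls))
  exact <- vapply(ret_ev, function(e) {
    co <- e$coordinates
    hit <- which(ret_calls$repeat1_start == co$repeat1_start &
                 ret_calls$repeat1_end == co$repeat1_end &
                 ret_calls$repeat2_start == co$repeat2_start &
                 ret_calls$repeat2_end == co$repeat2_end)
    if (length(hit)) matched_call[hit[1]] <<- TRUE
    length(hit) > 0L
  }, logical(1))

  in_region <- function(calls_df, co) {
    lo <- min(unlist(co)); hi <- max(unlist(co))
    calls_df$repeat1_start < hi & calls_df$repeat2_end > lo
  }
  decoy_ret <- 0L
  excised_any <- 0L
  for (e in ev) {
    if (e$event_type == "nahr_decoy" && nrow(ret_calls) &&
        any(in_region(ret_calls, e$coordinates))) {
      decoy_ret <- decoy_ret + 1L
    }
    if (e$event_type == "excised_junction" && nrow(calls) &&
        any(in_region(calls, e$coordinates))) {
      excised_any <- excised_any + 1L
    }
  }
  list(n_ret = length(ret_ev),
       n_ret_exact = sum(exact),
       recall = if (length(ret_ev)) sum(exact) / length(ret_ev) else NA_real_,
       false_ret_calls = sum(!matched_call),
       decoy_ret_calls = decoy_ret,
       excised_calls = excised_any,
       exact_by_event = exact)
}
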