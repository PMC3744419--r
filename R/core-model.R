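#' @importFrom utils read.delim write.table
NULL

.FEATURE_KINDS <- c("exon", "te_instance", "te_terminus", "target_site",
                    "primer", "probe", "restriction_site", "centromere",
                    "methylation_mark", "label")
.FEATURE_COLS <- c("chrom", "start", "end", "strand", "kind", "name", "attrs")

#' Construct a feature table
#'
#' Features use 0-based half-open coordinates. Zero-width features
#' (`start == end`) are allowed only for `centromere` and `target_site` point
#' marks. `attrs` is a free-form `key=value;key=value` string.
#'
#' @param chrom,start,end,strand,kind,name,attrs Vectors, recycled to a common
#'   length.
#' @return A `data.frame` with one row per feature, ordered by (start, end).
#' @export
features <- function(chrom = character(), start = integer(), end = integer(),
                     strand = "+", kind = "label", name = "", attrs = "") {
  if (length(start) == 0L) {
    chrom <- character(); end <- integer(); strand <- character()
    kind <- character(); name <- character(); attrs <- character()
  }
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = as.character(kind), name = as.character(name),
                   attrs = as.character(attrs), stringsAsFactors = FALSE)
  bad <- !df$kind %in% .FEATURE_KINDS
  if (any(bad)) {
    stop("unknown feature kind(s): ", paste(unique(df$kind[bad]), collapse = ", "),
         call. = FALSE)
  }
  df[order(df$start, df$end), , drop = FALSE]
}

# Single feature row (convenience).
.feat <- function(start, end, kind, name, strand = "+", attrs = "",
                  chrom = "chr") {
  features(chrom = chrom, start = start, end = end, strand = strand,
           kind = kind, name = name, attrs = attrs)
}

# Parse/format the attrs string.
.attrs_get <- function(attrs, key) {
  if (is.na(attrs) || !nzchar(attrs)) return(NA_character_)
  kv <- strsplit(attrs, ";", fixed = TRUE)[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  for (p in kv) if (length(p) == 2L && p[1] == key) return(p[2])
  NA_character_
}

.attrs_make <- function(...) {
  kv <- list(...)
  paste(sprintf("%s=%s", names(kv), vapply(kv, as.character, character(1))),
        collapse = ";")
}

#' Create a transposon definition
#'
#' Defines a mobile element by its consensus sequence and terminal inverted
#' repeat (TIR) lengths. Defaults follow the hAT family: 8 bp target site
#' duplication and 11 bp TIRs (the Ac TIR length).
#'
#' @param name,family Identifiers (name must be unique within a library).
#' @param sequence N-free consensus sequence.
#' @param tir5_len,tir3_len TIR lengths in bp; must sum to less than the
#'   consensus length.
#' @param tsd_len Target site duplication length in bp (>= 0).
#' @return An object of class `transposon_def`.
#' @export
transposon_def <- function(name, family, sequence, tir5_len = 11L,
                           tir3_len = 11L, tsd_len = 8L) {
  sequence <- .check_dna(sequence, allow_n = FALSE,
                         what = sprintf("TE consensus '%s'", name))
  tir5_len <- as.integer(tir5_len); tir3_len <- as.integer(tir3_len)
  tsd_len <- as.integer(tsd_len)
  if (tir5_len + tir3_len >= nchar(sequence)) {
    stop("tir5_len + tir3_len must be < consensus length", call. = FALSE)
  }
  if (tsd_len < 0L) stop("tsd_len must be >= 0", call. = FALSE)
  structure(list(name = name, family = family, sequence = sequence,
                 tir5_len = tir5_len, tir3_len = tir3_len, tsd_len = tsd_len),
            class = "transposon_def")
}

#' @export
print.transposon_def <- function(x, ...) {
  cat(sprintf("<transposon_def> %s (family %s, %d bp, TIR %d/%d, TSD %d)\n",
              x$name, x$family, nchar(x$sequence), x$tir5_len, x$tir3_len,
              x$tsd_len))
  invisible(x)
}

#' Load a transposon library from FASTA plus a metadata table
#'
#' The metadata TSV has columns `name`, `family`, `tir5_len`, `tir3_len`,
#' `tsd_len`; missing columns or rows fall back to defaults (`tsd_len = 8`,
#' TIR lengths 11, `family = name`). Every metadata row must have a matching
#' FASTA record; duplicate names are an error.
#'
#' @param fasta_path Path to the consensus FASTA.
#' @param metadata_path Optional path to the metadata TSV (may be empty).
#' @return Named list of [transposon_def()] objects.
#' @export
load_te_library <- function(fasta_path, metadata_path = NULL) {
  recs <- read_fasta(fasta_path)
  meta <- NULL
  if (!is.null(metadata_path) && file.exists(metadata_path) &&
      file.size(metadata_path) > 0L) {
    meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
    if (!"name" %in% names(meta)) {
      stop("TE metadata must have a 'name' column", call. = FALSE)
    }
    if (anyDuplicated(meta$name)) {
      stop("duplicate names in TE metadata", call. = FALSE)
    }
    missing <- setdiff(meta$name, names(recs))
    if (length(missing)) {
      stop("metadata rows without sequence: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  defs <- lapply(names(recs), function(nm) {
    row <- if (!is.null(meta) && nm %in% meta$name) {
      meta[meta$name == nm, , drop = FALSE]
    } else NULL
    getv <- function(col, default) {
      if (!is.null(row) && col %in% names(row) && !is.na(row[[col]][1])) {
        row[[col]][1]
      } else default
    }
    transposon_def(name = nm,
                   family = as.character(getv("family", nm)),
                   sequence = recs[[nm]]$sequence,
                   tir5_len = getv("tir5_len", 11L),
                   tir3_len = getv("tir3_len", 11L),
                   tsd_len = getv("tsd_len", 8L))
  })
  names(defs) <- names(recs)
  defs
}

#' Write a transposon library
#'
#' Companion writer to [load_te_library()]: consensus FASTA plus metadata TSV.
#' @param library Named list of [transposon_def()] objects.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_te_library <- function(library, fasta_path, metadata_path) {
  recs <- lapply(library, function(d) seq_record(d$name, d$sequence, d$family))
  write_fasta(recs, fasta_path)
  meta <- data.frame(name = vapply(library, `[[`, "", "name"),
                     family = vapply(library, `[[`, "", "family"),
                     tir5_len = vapply(library, `[[`, 1L, "tir5_len"),
                     tir3_len = vapply(library, `[[`, 1L, "tir3_len"),
                     tsd_len = vapply(library, `[[`, 1L, "tsd_len"))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Create a chromatid model
#'
#' A chromatid is one linear sequence plus an ordered feature table and a
#' centromere position. Exactly one `centromere` feature is kept in the table;
#' if absent it is added at `centromere_pos` as a zero-width point mark.
#'
#' @param record A [seq_record()] (or character sequence, then `id` is used).
#' @param features Feature table from [features()].
#' @param centromere_pos 0-based position of the centromere.
#' @param id Record id when `record` is a bare string.
#' @return Object of class `chromatid_model`.
#' @export
chromatid_model <- function(record, features = NULL, centromere_pos = 0L,
                            id = "chr") {
  if (is.character(record)) record <- seq_record(id, record)
  if (is.null(features)) {
    features <- .feat(integer(), integer(), character(), character())
  }
  centromere_pos <- as.integer(centromere_pos)
  if (!any(features$kind == "centromere")) {
    features <- rbind(features,
                      .feat(centromere_pos, centromere_pos, "centromere",
                            "centromere", chrom = record$id))
  }
  features$chrom <- record$id
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(record = record, features = features,
                 centromere_pos = centromere_pos),
            class = "chromatid_model")
}

#' @export
print.chromatid_model <- function(x, ...) {
  cat(sprintf("<chromatid_model> %s: %d bp, %d features, centromere @ %d\n",
              x$record$id, nchar(x$record$sequence), nrow(x$features),
              x$centromere_pos))
  invisible(x)
}

#' Define a target site on a sequence
#'
#' A target site is the `tsd_len`-bp substring at `pos`; upon transposon
#' insertion it is duplicated to both sides of the element.
#'
#' @param x Sequence carrier (chromatid, record, or string).
#' @param pos 0-based position of the first target base.
#' @param tsd_len Target length in bp (default 8, the hAT TSD).
#' @return Object of class `target_site` with fields `pos`, `tsd_len`, `seq`.
#' @export
target_site <- function(x, pos, tsd_len = 8L) {
  seq <- .as_sequence(x)
  pos <- as.integer(pos); tsd_len <- as.integer(tsd_len)
  s <- .substr0(seq, pos, pos + tsd_len)
  structure(list(pos = pos, tsd_len = tsd_len, seq = s), class = "target_site")
}

#' Extract a region from a chromatid or sequence
#'
#' 0-based half-open interval; for `strand = "-"` the reverse complement is
#' returned. Out-of-bounds coordinates are an error; `start == end` yields "".
#'
#' @param x Sequence carrier.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
extract_region <- function(x, start, end, strand = "+") {
  s <- .substr0(.as_sequence(x), as.integer(start), as.integer(end))
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Validate a chromatid model
#'
#' Checks the type invariants (bounds, ordering, zero-width rules, single
#' centromere, alphabet) and reports violations rather than erroring.
#'
#' @param chromatid A [chromatid_model()].
#' @return Character vector of violations; empty when the model is well-formed.
#' @export
validate_chromatid <- function(chromatid) {
  v <- character()
  seq <- chromatid$record$sequence
  n <- nchar(seq)
  if (!grepl("^[ACGTN]+$", seq)) v <- c(v, "sequence: non-ACGTN characters")
  fe <- chromatid$features
  if (nrow(fe)) {
    for (i in seq_len(nrow(fe))) {
      f <- fe[i, ]
      label <- sprintf("feature '%s' [%d,%d)", f$name, f$start, f$end)
      if (f$start < 0L || f$end > n) {
        v <- c(v, paste0(label, ": outside sequence bounds"))
      }
      if (f$start > f$end) v <- c(v, paste0(label, ": start > end"))
      if (f$start == f$end && !f$kind %in% c("centromere", "target_site")) {
        v <- c(v, paste0(label, ": zero-width not allowed for kind ", f$kind))
      }
    }
    if (is.unsorted(fe$start)) v <- c(v, "features: not sorted by start")
  }
  ncen <- sum(fe$kind == "centromere")
  if (ncen != 1L) v <- c(v, sprintf("centromere: expected 1 feature, found %d", ncen))
  v
}

# ---- BED6 / GFF3 ----------------------------------------------------------

#' Write features as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are written as-is.
#'
#' @param features Feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  df <- data.frame(features$chrom, features$start, features$end,
                   ifelse(nzchar(features$name), features$name, "."),
                   0L, features$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into a feature table
#'
#' Parsing goes through `rtracklayer::import`; zero-width records (kept by BED
#' as `start == end`) are read with a base parser since GRanges cannot hold
#' them.
#'
#' @param path BED file path.
#' @param kind Feature kind to assign (BED does not carry one).
#' @return Feature table.
#' @export
read_features_bed <- function(path, kind = "label") {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  zero <- raw$V2 == raw$V3
  out <- NULL
  if (any(!zero)) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else ""
    out <- features(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    strand = sub("\\*", "+", as.character(BiocGenerics::strand(gr))),
                    kind = kind, name = nm)
  }
  if (any(zero)) {
    z <- raw[zero, , drop = FALSE]
    out <- rbind(out, features(chrom = z$V1, start = z$V2, end = z$V3,
                               strand = if (ncol(z) >= 6) z$V6 else "+",
                               kind = kind,
                               name = if (ncol(z) >= 4) z$V4 else ""))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Write features as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' closed convention. Zero-width point marks are written as 1-bp intervals
#' anchored at the point (GFF3 cannot represent zero width); `kind` is stored
#' in the `type` column and `name`/`attrs` in column 9.
#'
#' @param features Feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  start1 <- features$start + 1L
  end1 <- features$end
  zero <- features$start == features$end
  end1[zero] <- start1[zero]  # point marks: 1 bp
  attr_col <- sprintf("Name=%s", features$name)
  extra <- nzchar(features$attrs)
  attr_col[extra] <- paste0(attr_col[extra], ";", features$attrs[extra])
  df <- data.frame(features$chrom, "retdup", features$kind, start1, end1, ".",
                   features$strand, ".", attr_col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Uses `rtracklayer::import`; converts back to 0-based half-open coordinates.
#'
#' @param path GFF3 path.
#' @return Feature table.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ""
  nm[is.na(nm)] <- ""
  kind <- as.character(gr$type)
  kind[!kind %in% .FEATURE_KINDS] <- "label"
  features(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = BiocGenerics::start(gr) - 1L,
           end = BiocGenerics::end(gr),
           strand = sub("\\*", "+", as.character(BiocGenerics::strand(gr))),
           kind = kind, name = nm)
}
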