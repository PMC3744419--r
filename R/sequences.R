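# Alphabet: genomes may contain N; transposon consensi must be N-free.
.DNA_CHARS <- c("A", "C", "G", "T", "N")

.check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  x <- toupper(x)
  ok <- if (allow_n) grepl("^[ACGTN]*$", x) else grepl("^[ACGT]*$", x)
  if (!ok) {
    stop(sprintf("%s contains non-IUPAC (or disallowed) characters", what),
         call. = FALSE)
  }
  x
}

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character strings over `{A,C,G,T,N}`; `N` complements to
#' `N`. An involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param x Character scalar, nucleotide sequence.
#' @return Character scalar, the reverse complement.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Create a sequence record
#'
#' A minimal container for one named nucleotide sequence. Sequences are
#' uppercased on ingest; characters outside `{A,C,G,T,N}` are an error.
#'
#' @param id Character scalar, unique identifier.
#' @param sequence Character scalar over `{A,C,G,T,N}` (lowercase accepted).
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `sequence`,
#'   `description`.
#' @export
seq_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  sequence <- .check_dna(sequence, allow_n = TRUE, what = sprintf("sequence '%s'", id))
  structure(list(id = id, sequence = sequence, description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp) %s\n", x$id, nchar(x$sequence),
              x$description))
  invisible(x)
}

#' Sequence length of a record, chromatid or string
#' @param x A `seq_record`, `chromatid_model`, or character scalar.
#' @return Integer length in bp.
#' @export
seq_length <- function(x) {
  nchar(.as_sequence(x))
}

# Coerce the various sequence carriers to a plain character string.
.as_sequence <- function(x) {
  if (inherits(x, "chromatid_model")) return(x$record$sequence)
  if (inherits(x, "seq_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(x)
  stop("cannot interpret object as a sequence", call. = FALSE)
}

# 0-based half-open substring.
.substr0 <- function(seq, start, end) {
  if (start > end) stop("start > end", call. = FALSE)
  if (start < 0L || end > nchar(seq)) stop("region out of bounds", call. = FALSE)
  if (start == end) return("")
  substr(seq, start + 1L, end)
}

#' Read a FASTA file into a list of sequence records
#'
#' @param path Path to a FASTA file.
#' @return Named list of [seq_record()] objects (names are record ids).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path, call. = FALSE)
  recs <- lapply(seq_along(ss), function(i) {
    seq_record(ids[i], as.character(ss[[i]]), desc[i])
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to a FASTA file
#'
#' @param records A `seq_record`, `chromatid_model`, or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, c("seq_record", "chromatid_model"))) {
    records <- list(records)
  }
  seqs <- vapply(records, .as_sequence, character(1))
  ids <- vapply(records, function(r) {
    if (inherits(r, "chromatid_model")) r$record$id else r$id
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}
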