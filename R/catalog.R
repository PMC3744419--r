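# Published allele catalog packaged as plain-text data.

#' Catalog of RET-generated duplication alleles
#'
#' The nine tandem direct duplication alleles recovered from the P1-ovov454
#' screen, with their duplication sizes (8157 bp to ~5.3 Mb). All share the
#' breakpoint in p1 intron 2; the second breakpoint differs per allele — the
#' overlapping, non-recurrent structure that distinguishes RET products from
#' NAHR products.
#'
#' @return data.frame with columns `allele`, `size_bp`, `size_printed`,
#'   `origin`.
#' @export
duplication_catalog <- function() {
  path <- system.file("extdata", "table1_duplications.tsv", package = "retdup")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Summary statistics of the duplication screen
#'
#' Combines the packaged allele catalog with the screen size (~2000 ears
#' examined, from which the nine catalogued duplication alleles derive) into
#' the headline numbers: catalog size, minimum duplication length, and the
#' duplication recovery frequency in percent.
#'
#' @param n_screened Number of ears screened.
#' @return List with `n_alleles`, `min_size_bp`, `max_size_bp`,
#'   `n_screened`, `frequency_pct` (unrounded) and `frequency_pct_rounded`
#'   (half-up to one decimal, the precision at which the frequency is usually
#'   quoted).
#' @export
catalog_stats <- function(n_screened = 2000L) {
  cat_df <- duplication_catalog()
  freq <- 100 * nrow(cat_df) / n_screened
  list(n_alleles = nrow(cat_df),
       min_size_bp = min(cat_df$size_bp),
       max_size_bp = max(cat_df$size_bp),
       n_screened = n_screened,
       frequency_pct = freq,
       frequency_pct_rounded = floor(freq * 10 + 0.5) / 10)
}
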