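# Small sequence / numeric helpers shared across modules.
# All genomic coordinates inside the package are 0-based half-open;
# conversion to/from the 1-based conventions of GTF and VCF happens only
# at the file boundary.

#' Reverse complement of a nucleotide string
#'
#' Alphabet A,C,G,T,N (uppercase). Used wherever minus-strand coding
#' sequence must be read in transcript orientation.
#'
#' @param x character scalar, nucleotide string.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# standard codon table; stops are "*". Taken from the canonical genetic code
# shipped with Biostrings so the mapping is never typed in by hand.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a CDS string codon by codon
#'
#' Trailing incomplete codons are dropped; codons containing N translate to
#' "X". Stops are "*". This is the package's single translation path; tests
#' check it against an independent translation route.
#'
#' @param cds character scalar of A/C/G/T/N.
#' @return character vector of single-letter amino acids (possibly empty).
#' @keywords internal
translate_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  codons <- substring(cds, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# split a CDS into codon strings (complete codons only)
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, by = 3L, length.out = n),
            seq(3L, by = 3L, length.out = n))
}

#' Round half-up to a number of decimal places
#'
#' Match-rate percentages are presented rounded half-up to 2 decimal places;
#' base round() rounds half-even, so reports use this helper instead.
#'
#' @param x numeric.
#' @param digits integer number of decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# overlap of footprint [s, e) with feature [a, b).
# Zero-width footprints (pure insertions, s == e) associate with the base to
# their left: the insertion point p sits inside [a, b) iff a < p <= b and the
# left neighbour base p-1 is in the feature, i.e. a <= p-1 < b.
overlaps_iv <- function(s, e, a, b) {
  if (s < e) s < b && e > a else (s - 1L) >= a && (s - 1L) < b
}

contained_iv <- function(s, e, a, b) {
  if (s < e) s >= a && e <= b else (s - 1L) >= a && (s - 1L) < b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vc_log <- function(fmt, ..., verbose = getOption("varconcord.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
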