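# Genome sequences, FASTA I/O and VCF reading/normalization.
#
# A genome is stored as a named character vector of uppercase chromosome
# sequences (class vc_genome). Variants are rows of a data.frame in the
# package's normalized representation: 0-based position of the first
# reference base, minimal left-aligned alleles (ref == "" for a pure
# insertion, alt == "" for a pure deletion).

#' Construct a genome object
#'
#' @param sequences named character vector or list, chromosome name ->
#'   nucleotide string. Sequences are uppercased and validated against the
#'   A/C/G/T/N alphabet.
#' @return object of class `vc_genome` (named character vector).
#' @export
genome_sequence <- function(sequences) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN bases in chromosome(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(sequences, class = "vc_genome")
}

#' @export
print.vc_genome <- function(x, ...) {
  cat(sprintf("<vc_genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return `vc_genome`. Sequences are uppercased; duplicate headers are an
#'   error.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  nm <- sub("\\s.*$", "", names(seqs))
  x <- as.character(seqs)
  names(x) <- nm
  g <- genome_sequence(x)
  vc_log("read_genome: %d sequence(s) from %s", length(g), path)
  g
}

#' Write a genome to FASTA
#'
#' @param genome `vc_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

genome_fetch <- function(genome, chrom, start, end) {
  # [start, end) 0-based half-open
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > nchar(genome[[chrom]]) || start > end)
    stop(sprintf("interval [%d,%d) outside %s", start, end, chrom))
  if (start == end) return("")
  substr(genome[[chrom]], start + 1L, end)
}

## ---- variants ----------------------------------------------------------

variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1L && la == 1L && ref != alt) "SNV"
  else if (lr == 0L && la > 0L) "insertion"
  else if (la == 0L && lr > 0L) "deletion"
  else "block_substitution"
}

#' Normalize a variant to its minimal left-aligned representation
#'
#' Trims the shared prefix and suffix of ref/alt, then left-shifts pure
#' indels while the base preceding the variant equals the last base of the
#' inserted/deleted sequence. Position is 0-based.
#'
#' @param chrom,pos,ref,alt variant fields (`pos` 0-based, anchor bases
#'   allowed).
#' @param genome `vc_genome` used for left-shifting.
#' @return list with fields `chrom`, `pos`, `ref`, `alt`, `var_class`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  ref <- toupper(ref); alt <- toupper(alt)
  # trim shared suffix
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == 0L && nchar(alt) == 0L)
    stop("ref == alt after normalization (monomorphic record)")
  # left-shift pure indels
  if (nchar(ref) == 0L || nchar(alt) == 0L) {
    seq_ <- if (nchar(ref) > 0L) ref else alt
    while (pos > 0L) {
      prev <- genome_fetch(genome, chrom, pos - 1L, pos)
      last <- substr(seq_, nchar(seq_), nchar(seq_))
      if (prev != last) break
      seq_ <- paste0(prev, substr(seq_, 1L, nchar(seq_) - 1L))
      pos <- pos - 1L
    }
    if (nchar(ref) > 0L) ref <- seq_ else alt <- seq_
  }
  if (nchar(ref) > 0L) {
    obs <- genome_fetch(genome, chrom, pos, pos + nchar(ref))
    if (obs != ref)
      stop(sprintf("REF mismatch at %s:%d — expected '%s', genome has '%s'",
                   chrom, pos, ref, obs))
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
       var_class = variant_class(ref, alt))
}

variant_df <- function(id, chrom, pos, ref, alt) {
  data.frame(variant_id = id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             var_class = mapply(variant_class, ref, alt, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Read variants from a VCF file
#'
#' Multi-allelic records are split into one variant per alternate allele;
#' anchor-base VCF representation is converted to the package's minimal
#' left-aligned form; REF alleles are checked against the genome. Symbolic
#' alternates (`<DEL>` etc.) are skipped with a warning count.
#'
#' @param path VCF file (v4.x).
#' @param genome `vc_genome`.
#' @return data.frame with columns `variant_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `var_class`.
#' @export
read_variants <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  ids0 <- names(SummarizedExperiment::rowRanges(vcf))
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  vcf <- VariantAnnotation::expand(vcf)     # drops names: re-derive ids
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)      # 1-based position of first REF base
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  ids <- if (is.null(ids0)) rep(NA_character_, length(rr)) else {
    ids0[nalt > 1L & !is.na(ids0) & ids0 != "."] <-
      NA_character_                       # multi-allelic: one id per alt
    rep(ids0, nalt)
  }
  symbolic <- grepl("^<", alt) | alt == "*" | grepl("[][]", alt)
  if (any(symbolic))
    warning(sum(symbolic), " symbolic allele record(s) skipped")
  keep <- which(!symbolic & nzchar(alt))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    nv <- normalize_variant(chrom[i], pos1[i] - 1L, ref[i], alt[i], genome)
    id <- if (is.na(ids[i]) || ids[i] == "." || !nzchar(ids[i]))
      sprintf("%s_%d_%s_%s", nv$chrom, nv$pos, nv$ref, nv$alt) else ids[i]
    out[[k]] <- data.frame(variant_id = id, chrom = nv$chrom, pos = nv$pos,
                           ref = nv$ref, alt = nv$alt,
                           var_class = nv$var_class,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- variant_df(character(0), character(0), integer(0),
                      character(0), character(0))
  vc_log("read_variants: %d variant(s) read, %d skipped from %s",
         nrow(res), sum(symbolic), path)
  res
}

#' Write variants to a VCF file with anchor bases
#'
#' The inverse boundary conversion of [read_variants()]: minimal
#' representation variants gain a left anchor base for indels and 1-based
#' positions.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param genome `vc_genome` (for anchor bases and contig headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genome, path) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(genome),
                     nchar(unclass(genome))),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(variants)) {
    recs <- character(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (v$var_class %in% c("insertion", "deletion")) {
        if (v$pos == 0L)
          stop("cannot anchor an indel at position 0: ", v$variant_id)
        anchor <- genome_fetch(genome, v$chrom, v$pos - 1L, v$pos)
        pos1 <- v$pos        # anchor base position, 1-based = (pos-1)+1
        ref <- paste0(anchor, v$ref)
        alt <- paste0(anchor, v$alt)
      } else {
        pos1 <- v$pos + 1L
        ref <- v$ref
        alt <- v$alt
      }
      recs[i] <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                         v$chrom, pos1, v$variant_id, ref, alt)
    }
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}
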