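# Transcript models (exon/CDS structure) and indexed transcript sets.
# Intervals are 0-based half-open matrices with columns start, end, stored
# in genomic order regardless of strand; strand is a flag.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix (n x 2) of 0-based half-open exon intervals,
#'   genomic order.
#' @param cds optional integer matrix of CDS intervals (same convention);
#'   `NULL` or zero rows for a non-coding transcript.
#' @return object of class `vc_transcript`. Coding transcripts whose total
#'   CDS length is not a multiple of 3 are flagged `cds_incomplete` (they are
#'   annotated best-effort, never rejected).
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop(transcript_id, ": empty exon interval")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop(transcript_id, ": overlapping exons")
  if (!is.null(cds) && length(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
      if (!inside)
        stop(transcript_id, ": CDS interval outside exons")
    }
  } else cds <- NULL
  cds_len <- if (is.null(cds)) 0L else sum(cds[, 2L] - cds[, 1L])
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = chrom,
    strand = strand,
    exons = exons,
    cds = cds,
    biotype = if (is.null(cds)) "noncoding" else "coding",
    cds_incomplete = cds_len > 0L && (cds_len %% 3L) != 0L
  ), class = "vc_transcript")
}

tx_span <- function(tx) c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])

# introns in genomic order: gaps between consecutive exons
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(start = tx$exons[-n, 2L], end = tx$exons[-1L, 1L])
}

#' @export
print.vc_transcript <- function(x, ...) {
  cat(sprintf("<vc_transcript %s> gene=%s %s:%d-%d(%s) %d exon(s), %s%s\n",
              x$transcript_id, x$gene_id, x$chrom, tx_span(x)[1L],
              tx_span(x)[2L], x$strand, nrow(x$exons), x$biotype,
              if (x$cds_incomplete) ", cds_incomplete" else ""))
  invisible(x)
}

#' Construct an indexed transcript set
#'
#' @param name set name (e.g. `"setA"`).
#' @param transcripts list of [transcript_model()] objects; ids must be
#'   unique.
#' @return object of class `vc_transcript_set` with a GRanges span index
#'   supporting overlap queries.
#' @export
transcript_set <- function(name, transcripts) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id in set '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  spans <- if (length(transcripts)) {
    sp <- t(vapply(transcripts, tx_span, integer(2L)))
    GenomicRanges::GRanges(
      seqnames = vapply(transcripts, `[[`, "", "chrom"),
      ranges = IRanges::IRanges(start = sp[, 1L] + 1L, end = sp[, 2L]))
  } else GenomicRanges::GRanges()
  structure(list(name = name, transcripts = transcripts, index = spans),
            class = "vc_transcript_set")
}

#' @export
print.vc_transcript_set <- function(x, ...) {
  nc <- sum(vapply(x$transcripts, function(t) t$biotype == "coding", TRUE))
  cat(sprintf("<vc_transcript_set %s> %d transcript(s) (%d coding)\n",
              x$name, length(x$transcripts), nc))
  invisible(x)
}

#' Transcripts overlapping (or flanking) a genomic interval
#'
#' @param tset `vc_transcript_set`.
#' @param chrom chromosome.
#' @param start,end 0-based half-open query interval (for a pure insertion
#'   pass the left-neighbour base, see the engine).
#' @param flank_bp widen the query by this many bases on each side (0 for a
#'   pure span query).
#' @return character vector of transcript ids, sorted.
#' @export
transcripts_at <- function(tset, chrom, start, end, flank_bp = 0L) {
  if (!length(tset$transcripts)) return(character(0))
  if (!chrom %in% GenomicRanges::seqnames(GenomeInfoDb::seqinfo(tset$index)))
    return(character(0))
  qs <- max(0L, start - flank_bp) + 1L
  qe <- max(end, start + 1L) + flank_bp   # ensure non-empty query
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(qs, qe))
  hits <- GenomicRanges::findOverlaps(q, tset$index)
  sort(names(tset$transcripts)[S4Vectors::subjectHits(hits)])
}

## ---- GTF I/O -----------------------------------------------------------

#' Read a transcript set from GTF
#'
#' Expects `exon` and `CDS` features carrying `transcript_id` and `gene_id`
#' attributes. 1-based inclusive GTF coordinates become 0-based half-open.
#' Transcripts whose CDS falls outside their exons are rejected with a
#' warning; a missing transcript_id is an error.
#'
#' @param path GTF file.
#' @param set_name name for the resulting set.
#' @return `vc_transcript_set`.
#' @export
read_transcripts <- function(path, set_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (!nrow(df)) return(transcript_set(set_name, list()))
  if (is.null(df$transcript_id) || anyNA(df$transcript_id))
    stop("GTF feature without transcript_id in ", path)
  gene_of <- tapply(as.character(df$gene_id), df$transcript_id,
                    function(g) g[1L])
  out <- list()
  skipped <- 0L
  for (txid in sort(unique(df$transcript_id))) {
    sub <- df[df$transcript_id == txid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cd <- sub[sub$type == "CDS", , drop = FALSE]
    exons <- cbind(ex$start - 1L, ex$end)     # GTF 1-based inclusive
    # merge book-ended/overlapping exon records
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    merged <- exons[1L, , drop = FALSE]
    if (nrow(exons) > 1L) for (i in 2L:nrow(exons)) {
      if (exons[i, 1L] <= merged[nrow(merged), 2L])
        merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], exons[i, 2L])
      else merged <- rbind(merged, exons[i, , drop = FALSE])
    }
    cds <- if (nrow(cd)) cbind(cd$start - 1L, cd$end) else NULL
    tx <- tryCatch(
      transcript_model(txid, unname(gene_of[[txid]]),
                       as.character(ex$seqnames[1L]),
                       as.character(ex$strand[1L]), merged, cds),
      error = function(e) {
        warning("transcript ", txid, " rejected: ", conditionMessage(e))
        NULL
      })
    if (is.null(tx)) skipped <- skipped + 1L else out[[txid]] <- tx
  }
  vc_log("read_transcripts: %d read, %d rejected from %s",
         length(out), skipped, path)
  transcript_set(set_name, out)
}

#' Write a transcript set to GTF
#'
#' Deterministic formatting (transcripts sorted by id) so identical sets
#' produce byte-identical files.
#'
#' @param tset `vc_transcript_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tset, path) {
  lines <- character(0)
  for (txid in sort(names(tset$transcripts))) {
    tx <- tset$transcripts[[txid]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     tx$gene_id, tx$transcript_id, tx$biotype)
    fmt <- function(type, iv)
      sprintf("%s\tvarconcord\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom, type, iv[, 1L] + 1L, iv[, 2L], tx$strand, attrs)
    lines <- c(lines, fmt("exon", tx$exons),
               if (!is.null(tx$cds)) fmt("CDS", tx$cds))
  }
  writeLines(lines, path)
  invisible(path)
}
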