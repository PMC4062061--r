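# Seeded synthetic data: genomes, paired transcript sets with controlled
# divergence (set B = set A plus extra genes), and variants with designed
# ground-truth consequences for every pipeline stage.
#
# Genome layout: [pad] gene gap gene gap ... [pad], genes non-overlapping,
# gaps wide enough (>= 2 * flank + margin) that extra-set-B genes sit in
# regions that are intergenic under set A. Randomness is drawn once from
# config$seed; variant placement itself is a deterministic scan (first
# feasible candidate), so identical configs give byte-identical outputs.

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

rand_seq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

r_int <- function(range) {
  if (range[1L] >= range[2L]) return(as.integer(range[1L]))
  sample(seq.int(range[1L], range[2L]), 1L)
}

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 20 shared
#' genes (about 15% non-coding), 25% extra set-B-only genes, 2-4 exons per
#' transcript, 50-90 codon CDSs, 150-400 bp introns, 2.2-3 kb intergenic
#' gaps (so flanking regions never touch), and 13 variants in each of the
#' 16 designed consequence classes (208 variants).
#'
#' @param seed integer RNG seed; identical seed + config gives
#'   byte-identical FASTA/GTF/VCF output.
#' @param chrom chromosome name.
#' @param n_genes number of genes shared by both transcript sets.
#' @param noncoding_fraction fraction of shared genes that are non-coding.
#' @param extra_transcript_fraction extra set-B-only genes, as a fraction of
#'   `n_genes`.
#' @param second_isoform_fraction fraction of shared coding genes carrying a
#'   second isoform (3'UTR-extended final exon, present in both sets).
#' @param exons_per_transcript,cds_codons,utr5_bp,utr3_bp,intron_bp,
#'   utr3_extension_bp integer ranges for gene structure draws.
#' @param min_exon_bp minimum exon length when splitting exonic sequence.
#' @param gap_bp intergenic gap range; must exceed `2 * flank + 200` so
#'   set-B-only genes are intergenic under set A.
#' @param pad_bp intergenic padding at the chromosome ends.
#' @param genome_length_bp optional total length; the genome is padded to
#'   it, and an error is raised if the layout does not fit.
#' @param class_mix named integer vector, designed class -> variant count.
#' @return list of class `vc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom = "chr1",
                       n_genes = 20L,
                       noncoding_fraction = 0.15,
                       extra_transcript_fraction = 0.25,
                       second_isoform_fraction = 0.3,
                       exons_per_transcript = c(2L, 4L),
                       cds_codons = c(50L, 90L),
                       utr5_bp = c(12L, 60L),
                       utr3_bp = c(12L, 60L),
                       intron_bp = c(150L, 400L),
                       utr3_extension_bp = c(150L, 300L),
                       min_exon_bp = 30L,
                       gap_bp = c(2200L, 3000L),
                       pad_bp = 3000L,
                       genome_length_bp = NULL,
                       class_mix = NULL) {
  if (is.null(class_mix))
    class_mix <- stats::setNames(rep(13L, 16L), c(
      "stop_loss_snv", "stop_retained_insertion", "stop_gain_snv",
      "frameshift_indel", "inframe_indel", "missense_snv", "synonymous_snv",
      "splice_donor_snv", "splice_acceptor_snv", "splice_region_snv",
      "deep_intronic_snv", "utr5_snv", "utr3_snv", "intergenic_snv",
      "initiator_codon_snv", "stopgain_via_indel"))
  stopifnot(noncoding_fraction >= 0, noncoding_fraction <= 1,
            extra_transcript_fraction >= 0, extra_transcript_fraction <= 1,
            second_isoform_fraction >= 0, second_isoform_fraction <= 1,
            all(class_mix >= 0L))
  structure(as.list(environment()), class = "vc_sim_config")
}

# transcript-orientation gene body: exon/intron layout, sequence, local
# coordinates (0-based within the gene block, transcript orientation)
build_gene_body <- function(cfg, coding) {
  if (coding) {
    k <- r_int(cfg$cds_codons)               # codons incl start and stop
    cds_seq <- paste0("ATG",
                      paste(sample(NONSTOP_CODONS, k - 2L, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    u5 <- r_int(cfg$utr5_bp); u3 <- r_int(cfg$utr3_bp)
    exonic <- paste0(rand_seq(u5), cds_seq, rand_seq(u3))
  } else {
    u5 <- u3 <- 0L
    exonic <- rand_seq(r_int(c(200L, 500L)))
  }
  elen <- nchar(exonic)
  E <- r_int(cfg$exons_per_transcript)
  E <- max(2L, min(E, elen %/% cfg$min_exon_bp))
  extra <- elen - E * cfg$min_exon_bp
  bars <- if (E > 1L) sort(sample.int(extra + 1L, E - 1L, replace = TRUE) - 1L)
          else integer(0)
  parts <- diff(c(0L, bars, extra)) + cfg$min_exon_bp
  introns <- if (E > 1L) vapply(seq_len(E - 1L), function(i)
    r_int(cfg$intron_bp), 1L) else integer(0)
  # assemble local sequence and exon intervals
  seq_parts <- character(0)
  exons <- matrix(0L, E, 2L)
  cursor <- 0L; t_off <- 0L
  for (i in seq_len(E)) {
    exons[i, ] <- c(cursor, cursor + parts[i])
    seq_parts <- c(seq_parts, substr(exonic, t_off + 1L, t_off + parts[i]))
    cursor <- cursor + parts[i]; t_off <- t_off + parts[i]
    if (i < E) {
      seq_parts <- c(seq_parts, rand_seq(introns[i]))
      cursor <- cursor + introns[i]
    }
  }
  body <- paste(seq_parts, collapse = "")
  # CDS local intervals: transcript-range [u5, u5 + cds) across exons
  cds <- NULL
  if (coding) {
    lo <- u5; hi <- u5 + nchar(exonic) - u5 - u3
    t0 <- 0L
    rows <- list()
    for (i in seq_len(E)) {
      a <- t0; b <- t0 + parts[i]            # transcript coords of exon i
      s <- max(a, lo); e <- min(b, hi)
      if (s < e) rows[[length(rows) + 1L]] <-
          c(exons[i, 1L] + (s - a), exons[i, 1L] + (e - a))
      t0 <- b
    }
    cds <- do.call(rbind, rows)
  }
  list(seq = body, len = nchar(body), exons = exons, cds = cds,
       u5 = u5, u3 = u3)
}

# map local (transcript-orientation) intervals onto the genome
map_iv <- function(iv, start, total, strand) {
  if (is.null(iv)) return(NULL)
  out <- if (strand == "+") cbind(start + iv[, 1L], start + iv[, 2L])
         else cbind(start + total - iv[, 2L], start + total - iv[, 1L])
  out[order(out[, 1L]), , drop = FALSE]
}

#' Simulate a genome with two overlapping transcript sets
#'
#' Every coding transcript has an ATG start, an in-frame stop, internal
#' codons free of stops and CDS length a multiple of 3. Set B contains all
#' of set A plus `extra_transcript_fraction * n_genes` extra genes placed in
#' gaps that are intergenic under set A.
#'
#' @param config [sim_config()].
#' @param outdir if given, writes `genome.fa`, `setA.gtf`, `setB.gtf`.
#' @return list of class `vc_simulation`: `genome`, `set_a`, `set_b`,
#'   `genes` (layout table), `gaps`, `config`.
#' @export
simulate_genome_and_transcripts <- function(config = sim_config(),
                                            outdir = NULL) {
  set.seed(config$seed)
  cfg <- config
  n_nc <- round(cfg$noncoding_fraction * cfg$n_genes)
  nc_idx <- if (n_nc > 0L) unique(round(seq(2, max(2, cfg$n_genes - 1L),
                                            length.out = n_nc)))
            else integer(0)
  n_bonly <- round(cfg$extra_transcript_fraction * cfg$n_genes)
  bonly_after <- if (n_bonly > 0L)
    unique(round(seq(3, cfg$n_genes, length.out = n_bonly)))
  else integer(0)

  chrom <- cfg$chrom
  parts <- character(0)
  cursor <- 0L
  pad <- rand_seq(cfg$pad_bp)
  parts <- c(parts, pad); cursor <- cursor + cfg$pad_bp
  shared <- list(); bonly <- list()
  genes <- list(); gaps <- list()
  gap_start <- 0L

  emit_gene <- function(gid, coding, strand, shared_set) {
    body <- build_gene_body(cfg, coding)
    iso2 <- coding && shared_set &&
      stats::runif(1L) < cfg$second_isoform_fraction
    ext <- if (iso2) r_int(cfg$utr3_extension_bp) else 0L
    total <- body$len + ext
    seq_local <- paste0(body$seq, rand_seq(ext))
    gseq <- if (strand == "+") seq_local else revcomp(seq_local)
    exons_g <- map_iv(body$exons, cursor, total, strand)
    cds_g <- map_iv(body$cds, cursor, total, strand)
    txs <- list(transcript_model(paste0(gid, ".T1"), gid, chrom, strand,
                                 exons_g, cds_g))
    if (iso2) {
      ex2 <- body$exons
      ex2[nrow(ex2), 2L] <- body$len + ext     # extend final exon
      txs[[2L]] <- transcript_model(paste0(gid, ".T2"), gid, chrom, strand,
                                    map_iv(ex2, cursor, total, strand), cds_g)
    }
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gid, coding = coding, shared = shared_set, strand = strand,
      start = cursor, end = cursor + total, stringsAsFactors = FALSE)
    parts <<- c(parts, gseq)
    cursor <<- cursor + total
    txs
  }
  close_gap <- function() {
    g <- r_int(cfg$gap_bp)
    gaps[[length(gaps) + 1L]] <<- c(cursor, cursor + g)
    parts <<- c(parts, rand_seq(g))
    cursor <<- cursor + g
  }

  gaps[[1L]] <- c(0L, cfg$pad_bp)
  bj <- 0L
  for (i in seq_len(cfg$n_genes)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    shared <- c(shared, emit_gene(sprintf("G%03d", i), !(i %in% nc_idx),
                                  strand, TRUE))
    close_gap()
    if (i %in% bonly_after) {
      bj <- bj + 1L
      bonly <- c(bonly, emit_gene(sprintf("GB%02d", bj), TRUE,
                                  if (bj %% 2L == 1L) "-" else "+", FALSE))
      close_gap()
    }
  }
  parts <- c(parts, rand_seq(cfg$pad_bp))
  gaps[[length(gaps) + 1L]] <- c(cursor, cursor + cfg$pad_bp)
  cursor <- cursor + cfg$pad_bp
  seq_full <- paste(parts, collapse = "")
  if (!is.null(cfg$genome_length_bp)) {
    if (cursor > cfg$genome_length_bp)
      stop(sprintf("layout needs %d bp but genome_length_bp = %d",
                   cursor, cfg$genome_length_bp))
    seq_full <- paste0(seq_full, rand_seq(cfg$genome_length_bp - cursor))
  }
  genome <- genome_sequence(stats::setNames(seq_full, chrom))
  set_a <- transcript_set("setA", shared)
  set_b <- transcript_set("setB", c(shared, bonly))
  sim <- structure(list(
    genome = genome, set_a = set_a, set_b = set_b,
    genes = do.call(rbind, genes),
    gaps = do.call(rbind, gaps),
    config = cfg), class = "vc_simulation")
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' @export
print.vc_simulation <- function(x, ...) {
  cat(sprintf("<vc_simulation> %s bp genome, %d shared + %d B-only gene(s)\n",
              format(nchar(unclass(x$genome)[[1]]), big.mark = ","),
              sum(x$genes$shared), sum(!x$genes$shared)))
  invisible(x)
}

#' Write simulation outputs (FASTA + two GTFs)
#'
#' @param sim `vc_simulation`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(outdir, "genome.fa"))
  write_transcripts(sim$set_a, file.path(outdir, "setA.gtf"))
  write_transcripts(sim$set_b, file.path(outdir, "setB.gtf"))
  invisible(outdir)
}
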