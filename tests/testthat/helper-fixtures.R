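# Hand-built fixtures and independent oracles shared across the test files.
# The fixture transcript is small enough to reason about by hand:
#
#   chrT (721 bp), transcript TX1 on "+":
#     exon1 [10,31): 6 bp 5'UTR + first 15 CDS bases
#     intron [31,100)
#     exon2 [100,121): last 15 CDS bases + 6 bp 3'UTR
#   CDS (30 bp): ATG GCT TTG CAT CCG GAT AAA CAC GAA TGA
#   CDS genomic intervals [16,31) and [100,115); stop codon at 112..114.

FIX_CDS <- "ATGGCTTTGCATCCGGATAAACACGAATGA"

fixture_genome <- function() {
  seq <- paste0(
    strrep("A", 10),
    "ACACAC", substr(FIX_CDS, 1, 15),                 # exon1 [10,31)
    "GT", strrep("CT", 32), "C", "AG",                # intron [31,100)
    substr(FIX_CDS, 16, 30), "GTGTGT",                # exon2 [100,121)
    strrep("TGCA", 150))                              # [121,721)
  genome_sequence(c(chrT = seq))
}

fixture_tx <- function() {
  transcript_model("TX1", "GX", "chrT", "+",
                   exons = rbind(c(10L, 31L), c(100L, 121L)),
                   cds = rbind(c(16L, 31L), c(100L, 115L)))
}

snv <- function(pos, ref, alt, id = sprintf("s%d", pos), chrom = "chrT")
  data.frame(variant_id = id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, var_class = "SNV",
             stringsAsFactors = FALSE)

indel <- function(pos, ref, alt, id = sprintf("i%d", pos), chrom = "chrT") {
  vc <- if (nchar(ref) == 0) "insertion" else if (nchar(alt) == 0) "deletion"
        else "block_substitution"
  data.frame(variant_id = id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, var_class = vc, stringsAsFactors = FALSE)
}

fixture_snv_at <- function(g, pos, alt = NULL) {
  ref <- substr(unclass(g)[["chrT"]], pos + 1, pos + 1)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snv(pos, ref, alt)
}

## ---- strand mirroring --------------------------------------------------

rc_str <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

mirror_genome <- function(g) {
  s <- vapply(unclass(g), rc_str, "")
  genome_sequence(s)
}

mirror_tx <- function(tx, N) {
  flip <- function(iv) {
    out <- cbind(N - iv[, 2L], N - iv[, 1L])
    out[order(out[, 1L]), , drop = FALSE]
  }
  transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                   if (tx$strand == "+") "-" else "+",
                   flip(tx$exons), if (is.null(tx$cds)) NULL else flip(tx$cds))
}

mirror_variant <- function(v, N, genome_m) {
  lr <- nchar(v$ref)
  pos <- if (lr == 0) N - v$pos else N - (v$pos + lr)
  nv <- normalize_variant(v$chrom, pos, rc_str(v$ref), rc_str(v$alt),
                          genome_m)
  data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = nv$pos,
             ref = nv$ref, alt = nv$alt, var_class = nv$var_class,
             stringsAsFactors = FALSE)
}

## ---- independent coding oracle -----------------------------------------

# Brute-force route: edit the whole chromosome string, shift the CDS
# intervals, extract and translate both CDSs with Biostrings, and decide an
# abstract consequence label from the protein comparison alone.
bio_translate <- function(s) {
  n <- (nchar(s) %/% 3) * 3
  if (n == 0) return(character(0))
  strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1, n)), no.init.codon = TRUE)), "")[[1]]
}

oracle_coding_label <- function(v, tx, genome, regime) {
  chromseq <- unclass(genome)[[v$chrom]]
  shift <- nchar(v$alt) - nchar(v$ref)
  altseq <- paste0(substr(chromseq, 1, v$pos), v$alt,
                   substr(chromseq, v$pos + nchar(v$ref) + 1, nchar(chromseq)))
  iv <- tx$cds
  iv2 <- iv
  for (i in seq_len(nrow(iv2))) {
    if (iv2[i, 1L] > v$pos) iv2[i, ] <- iv2[i, ] + shift
    else if (iv2[i, 2L] > v$pos) iv2[i, 2L] <- iv2[i, 2L] + shift
  }
  get_cds <- function(s, iv) {
    x <- paste(vapply(seq_len(nrow(iv)), function(i)
      substr(s, iv[i, 1L] + 1, iv[i, 2L]), ""), collapse = "")
    if (tx$strand == "-") rc_str(x) else x
  }
  ref_cds <- get_cds(chromseq, iv)
  alt_cds <- get_cds(altseq, iv2)
  pr <- bio_translate(ref_cds); pa <- bio_translate(alt_cds)
  sr <- match("*", pr); sa <- match("*", pa)
  retained <- !is.na(sr) && !is.na(sa) && sa == sr &&
    identical(pr[seq_len(sr - 1)], pa[seq_len(sa - 1)])
  first_codon_hit <- v$var_class == "SNV" &&
    substr(ref_cds, 1, 3) == "ATG" && substr(alt_cds, 1, 3) != "ATG"
  if (first_codon_hit) return("initiator")
  if (shift %% 3 != 0) {
    premature <- !is.na(sa) && sa < length(pa)
    if (regime$stop_retained_detection && retained) return("syn_or_retained")
    if (regime$stop_scan_indels && premature) return("stop_gain")
    return("frameshift")
  }
  if (regime$stop_retained_detection && retained) return("syn_or_retained")
  expected <- if (!is.na(sr)) sr + shift %/% 3 else NA
  if (!is.na(sa) && !is.na(expected) && sa < expected) {
    if (v$var_class == "SNV" || regime$stop_scan_indels) return("stop_gain")
  }
  if (!is.na(sr) && (is.na(sa) || is.na(expected) || sa != expected))
    return("stop_loss")
  if (shift != 0) return("inframe")
  if (identical(pr, pa)) return("syn_or_retained")
  "missense"
}

# which abstract oracle labels each engine term is allowed to realize
term_matches_label <- function(term, label) {
  allowed <- switch(term,
    stopgain_SNV = , stop_gained = "stop_gain",
    stoploss_SNV = , stop_lost = "stop_loss",
    synonymous_SNV = , synonymous_variant = ,
    stop_retained_variant = "syn_or_retained",
    nonsynonymous_SNV = c("missense", "initiator"),
    missense_variant = "missense",
    initiator_codon_variant = "initiator",
    frameshift_insertion = , frameshift_deletion = ,
    frameshift_substitution = , frameshift_variant = "frameshift",
    nonframeshift_insertion = , nonframeshift_deletion = ,
    nonframeshift_substitution = , inframe_insertion = ,
    inframe_deletion = "inframe",
    unknown = "unknown",
    character(0))
  label %in% allowed
}

## ---- cached simulation fixtures ----------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

get_sim <- function() cached("sim", function()
  simulate_genome_and_transcripts(sim_config(seed = 101)))

get_truth_run <- function() cached("truth_run", function() {
  sim <- get_sim()
  vt <- simulate_variants(sim)
  list(sim = sim, vt = vt,
       calls_a = annotate_variants(vt$variants, sim$set_a, sim$genome,
                                   a_style_regime()),
       calls_v = annotate_variants(vt$variants, sim$set_a, sim$genome,
                                   v_style_regime()))
})

get_scenario <- function() cached("scenario", function() {
  sc <- make_discordance_scenario(sim_config(seed = 202))
  run <- run_comparison(sc$sim$genome, sc$variants, "two_transcript_sets",
                        tset_a = sc$sim$set_a, tset_b = sc$sim$set_b,
                        regime_a = sc$regime)
  list(sc = sc, run = run)
})
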