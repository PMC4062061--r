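# Designed-variant placement: each variant is positioned by construction to
# realize its consequence class in its target transcript, scanning candidate
# positions in deterministic order and taking the first feasible one (no
# rejection sampling, so generation is reproducible by scan order alone).

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# translation-order CDS info for a coding transcript
tx_cds_info <- function(tx, genome) {
  gp <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
    seq.int(tx$cds[i, 1L], tx$cds[i, 2L] - 1L)))
  if (tx$strand == "-") gp <- rev(gp)
  cds <- cds_concat(tx, genome)
  if (tx$strand == "-") cds <- revcomp(cds)
  list(cds = cds, map = gp, k = nchar(cds) %/% 3L)
}

tx_exon_map <- function(tx) {
  gp <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq.int(tx$exons[i, 1L], tx$exons[i, 2L] - 1L)))
  if (tx$strand == "-") gp <- rev(gp)
  gp
}

# 1-based distance from base p to the nearest exon/intron boundary
dist_junction <- function(tx, p) {
  iv <- tx_introns(tx)
  if (!nrow(iv)) return(Inf)
  js <- c(iv[, 1L], iv[, 2L])
  min(vapply(js, function(j) if (p >= j) p - j + 1L else j - p, 1L))
}

# genomic record for a transcript-orientation base substitution at
# translation/exon-map position g (genomic), transcript-alt base alt_t
snv_record <- function(genome, tx, g, alt_t) {
  ref <- genome_fetch(genome, tx$chrom, g, g + 1L)
  alt <- if (tx$strand == "+") alt_t else comp_base(alt_t)
  if (ref == alt) return(NULL)
  list(pos = g, ref = ref, alt = alt)
}

# genomic record for an insertion of transcript-orientation sequence ins_t
# before translation position t (map = translation-order genomic positions)
ins_record <- function(tx, map, t, ins_t) {
  if (tx$strand == "+") list(pos = map[t + 1L], ref = "", alt = ins_t)
  else list(pos = map[t + 1L] + 1L, ref = "", alt = revcomp(ins_t))
}

# premature stop under the full-frame re-translation rule
is_premature <- function(alt_cds) {
  aa <- translate_codons(alt_cds)
  st <- match("*", aa)
  !is.na(st) && st < length(aa)
}

edit_cds <- function(cds, t, nref, alt) {
  paste0(substr(cds, 1L, t), alt, substr(cds, t + nref + 1L, nchar(cds)))
}

#' Simulate variants with designed ground-truth consequences
#'
#' Places `config$class_mix` variants over the shared coding transcripts
#' (and intergenic gaps) of a simulation, each constructed so that its
#' consequence class holds in its target transcript under the reference
#' regime semantics, and returns the truth table alongside.
#'
#' @param sim output of [simulate_genome_and_transcripts()].
#' @param class_mix named counts per designed class (defaults to the
#'   simulation config's mix).
#' @param outdir if given, writes `variants.vcf` and `truth.tsv`.
#' @return list with `variants` (normalized variant data.frame) and `truth`
#'   (one row per variant: designed class, target transcript, expected term
#'   under each regime, expected high-level categories).
#' @export
simulate_variants <- function(sim, class_mix = NULL, outdir = NULL) {
  cfg <- sim$config
  if (is.null(class_mix)) class_mix <- cfg$class_mix
  genome <- sim$genome
  chrom <- cfg$chrom
  shared_genes <- sim$genes[sim$genes$shared & sim$genes$coding, ,
                            drop = FALSE]
  txs <- lapply(paste0(shared_genes$gene_id, ".T1"),
                function(id) sim$set_a$transcripts[[id]])
  info <- lapply(txs, tx_cds_info, genome = genome)
  n_tx <- length(txs)
  if (!n_tx) stop("no shared coding transcripts to host variants")

  used <- character(0)
  vars <- list(); truth <- list()
  counter <- 0L

  add_variant <- function(class, pos, ref, alt, tx_id, exp_a, exp_v,
                          require_stable = TRUE, accept = NULL) {
    nv <- tryCatch(normalize_variant(chrom, pos, ref, alt, genome),
                   error = function(e) NULL)
    if (is.null(nv)) return(FALSE)
    if (require_stable &&
        !(nv$pos == pos && nv$ref == ref && nv$alt == alt)) return(FALSE)
    if (!is.null(accept) && !accept(nv)) return(FALSE)
    key <- paste(nv$pos, nv$ref, nv$alt)
    if (key %in% used) return(FALSE)
    used <<- c(used, key)
    counter <<- counter + 1L
    id <- sprintf("v%03d_%s", counter, class)
    vars[[length(vars) + 1L]] <<-
      variant_df(id, chrom, nv$pos, nv$ref, nv$alt)
    truth[[length(truth) + 1L]] <<- data.frame(
      variant_id = id, class = class, chrom = chrom, pos = nv$pos,
      ref = nv$ref, alt = nv$alt, target_transcript = tx_id,
      expected_a = exp_a, expected_v = exp_v,
      category_a = term_category(exp_a, "A_style"),
      category_v = term_category(exp_v, "V_style"),
      stringsAsFactors = FALSE)
    TRUE
  }

  BASES <- c("A", "C", "G", "T")
  tab <- codon_table()

  # scan one transcript for one instance of a CDS SNV class;
  # test(ref_codon, alt_codon, ci) decides class membership
  place_cds_snv <- function(ti, class, exp_a, exp_v, codon_lo, codon_hi,
                            test) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    codons <- split_codons(ii$cds)
    for (ci in seq.int(codon_lo, min(codon_hi, ii$k - 1L))) {
      rc <- codons[ci + 1L]
      for (j in 0:2) {
        t <- 3L * ci + j
        g <- ii$map[t + 1L]
        if (dist_junction(tx, g) <= 8L) next
        for (b in BASES) {
          if (b == substr(rc, j + 1L, j + 1L)) next
          ac <- rc
          substr(ac, j + 1L, j + 1L) <- b
          if (!test(rc, ac, ci)) next
          rec <- snv_record(genome, tx, g, b)
          if (is.null(rec)) next
          if (add_variant(class, rec$pos, rec$ref, rec$alt,
                          tx$transcript_id, exp_a, exp_v)) return(TRUE)
        }
      }
    }
    FALSE
  }

  place_one <- function(class, inst) {
    start <- (inst - 1L) %% n_tx
    for (off in seq_len(n_tx)) {
      ti <- ((start + off - 1L) %% n_tx) + 1L
      tx <- txs[[ti]]; ii <- info[[ti]]
      ok <- switch(class,
        stop_loss_snv = place_cds_snv(ti, class, "stoploss_SNV", "stop_lost",
          ii$k - 1L, ii$k - 1L,
          function(rc, ac, ci) rc %in% STOP_CODONS && !(ac %in% STOP_CODONS)),
        stop_gain_snv = place_cds_snv(ti, class, "stopgain_SNV", "stop_gained",
          1L, ii$k - 2L,
          function(rc, ac, ci) !(rc %in% STOP_CODONS) && ac %in% STOP_CODONS),
        missense_snv = place_cds_snv(ti, class, "nonsynonymous_SNV",
          "missense_variant", 1L, ii$k - 2L,
          function(rc, ac, ci) !(ac %in% STOP_CODONS) &&
            tab[[rc]] != tab[[ac]]),
        synonymous_snv = place_cds_snv(ti, class, "synonymous_SNV",
          "synonymous_variant", 1L, ii$k - 2L,
          function(rc, ac, ci) !(rc %in% STOP_CODONS) &&
            tab[[rc]] == tab[[ac]]),
        initiator_codon_snv = place_cds_snv(ti, class, "nonsynonymous_SNV",
          "initiator_codon_variant", 0L, 0L,
          function(rc, ac, ci) rc == "ATG" && ac != "ATG"),
        stop_retained_insertion = place_stop_retained(ti),
        frameshift_indel = place_frameshift(ti, inst),
        stopgain_via_indel = place_stopgain_indel(ti),
        inframe_indel = place_inframe(ti, inst),
        splice_donor_snv = place_splice(ti, "donor"),
        splice_acceptor_snv = place_splice(ti, "acceptor"),
        splice_region_snv = place_splice(ti, "region"),
        deep_intronic_snv = place_deep_intronic(ti),
        utr5_snv = place_utr(ti, five = TRUE),
        utr3_snv = place_utr(ti, five = FALSE),
        stop("unknown designed class: ", class))
      if (ok) return(TRUE)
    }
    FALSE
  }

  # insertion inside (or at) the stop codon that leaves a stop codon at the
  # same protein position; candidates are rejected when left-alignment
  # shifts the insertion out of the CDS (where the footprint would no
  # longer touch the coding sequence)
  place_stop_retained <- function(ti) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    L <- 3L * ii$k
    s <- substring(ii$cds, L - 2L, L)          # the stop codon
    in_cds <- function(nv) any(apply(tx$cds, 1L, function(iv)
      contained_iv(nv$pos, nv$pos + nchar(nv$ref), iv[1L], iv[2L])))
    for (j in c(2L, 1L, 0L)) {
      for (X in BASES) {
        first3 <- switch(as.character(j),
                         "0" = paste0(X, substr(s, 1L, 2L)),
                         "1" = paste0(substr(s, 1L, 1L), X, substr(s, 2L, 2L)),
                         "2" = paste0(substr(s, 1L, 2L), X))
        if (!(first3 %in% STOP_CODONS)) next
        t <- L - 3L + j
        g <- ii$map[t + 1L]
        if (dist_junction(tx, g) <= 8L) next
        rec <- ins_record(tx, ii$map, t, X)
        if (add_variant("stop_retained_insertion", rec$pos, rec$ref,
                        rec$alt, tx$transcript_id, "synonymous_SNV",
                        "stop_retained_variant", require_stable = FALSE,
                        accept = in_cds)) return(TRUE)
      }
    }
    FALSE
  }

  place_frameshift <- function(ti, inst) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    del <- inst %% 2L == 1L
    lo <- 3L * max(2L, (2L * ii$k) %/% 3L)
    hi <- 3L * (ii$k - 1L) - 1L
    for (t in seq.int(lo, hi - 1L)) {
      g <- ii$map[t + 1L]
      if (dist_junction(tx, g) <= 8L) next
      if (del) {
        alt_cds <- edit_cds(ii$cds, t, 1L, "")
        if (is_premature(alt_cds)) next
        ref <- genome_fetch(genome, chrom, g, g + 1L)
        if (add_variant("frameshift_indel", g, ref, "", tx$transcript_id,
                        "frameshift_deletion", "frameshift_variant"))
          return(TRUE)
      } else {
        for (b in BASES) {
          alt_cds <- edit_cds(ii$cds, t, 0L, b)
          if (is_premature(alt_cds)) next
          rec <- ins_record(tx, ii$map, t, b)
          if (add_variant("frameshift_indel", rec$pos, rec$ref, rec$alt,
                          tx$transcript_id, "frameshift_insertion",
                          "frameshift_variant")) return(TRUE)
        }
      }
    }
    FALSE
  }

  place_stopgain_indel <- function(ti) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    for (t in seq.int(6L, max(6L, 3L * (ii$k %/% 2L)))) {
      g <- ii$map[t + 1L]
      if (dist_junction(tx, g) <= 8L) next
      alt_cds <- edit_cds(ii$cds, t, 1L, "")
      if (!is_premature(alt_cds)) next
      ref <- genome_fetch(genome, chrom, g, g + 1L)
      if (add_variant("stopgain_via_indel", g, ref, "", tx$transcript_id,
                      "stopgain_SNV", "frameshift_variant")) return(TRUE)
    }
    FALSE
  }

  place_inframe <- function(ti, inst) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    del <- inst %% 2L == 1L
    for (ci in seq.int(2L, ii$k - 3L)) {
      t <- 3L * ci
      gs <- ii$map[c(t + 1L, t + 2L, t + 3L)]
      if (min(vapply(gs, dist_junction, 1, tx = tx)) <= 8L) next
      if (max(gs) - min(gs) != 2L) next        # single-exon run
      if (del) {
        g0 <- min(gs)
        ref <- genome_fetch(genome, chrom, g0, g0 + 3L)
        alt_cds <- edit_cds(ii$cds, t, 3L, "")
        if (is_premature(alt_cds)) next
        if (add_variant("inframe_indel", g0, ref, "", tx$transcript_id,
                        "nonframeshift_deletion", "inframe_deletion"))
          return(TRUE)
      } else {
        for (ins in c("GCA", "GAC", "TCC")) {
          rec <- ins_record(tx, ii$map, t, ins)
          if (add_variant("inframe_indel", rec$pos, rec$ref, rec$alt,
                          tx$transcript_id, "nonframeshift_insertion",
                          "inframe_insertion")) return(TRUE)
        }
      }
    }
    FALSE
  }

  place_splice <- function(ti, kind) {
    tx <- txs[[ti]]
    iv <- tx_introns(tx)
    exp <- switch(kind,
                  donor = c("splicing", "splice_donor_variant"),
                  acceptor = c("splicing", "splice_acceptor_variant"),
                  region = c("splicing", "splice_region_variant"))
    cls <- paste0("splice_", kind, "_snv")
    for (i in seq_len(nrow(iv))) {
      is_ <- iv[i, 1L]; ie <- iv[i, 2L]
      if (ie - is_ < 20L) next
      g <- switch(kind,
                  donor = if (tx$strand == "+") is_ else ie - 1L,
                  acceptor = if (tx$strand == "+") ie - 1L else is_,
                  region = is_ + 4L)
      if (kind == "region" && (ie - g) <= 8L) next
      ref <- genome_fetch(genome, chrom, g, g + 1L)
      for (b in setdiff(BASES, ref)) {
        if (add_variant(cls, g, ref, b, tx$transcript_id, exp[1L], exp[2L]))
          return(TRUE)
      }
    }
    FALSE
  }

  place_deep_intronic <- function(ti) {
    tx <- txs[[ti]]
    iv <- tx_introns(tx)
    for (i in seq_len(nrow(iv))) {
      g <- iv[i, 1L] + (iv[i, 2L] - iv[i, 1L]) %/% 2L
      if (dist_junction(tx, g) <= 8L) next
      ref <- genome_fetch(genome, chrom, g, g + 1L)
      if (add_variant("deep_intronic_snv", g, ref,
                      setdiff(BASES, ref)[1L], tx$transcript_id,
                      "intronic", "intron_variant")) return(TRUE)
    }
    FALSE
  }

  place_utr <- function(ti, five) {
    tx <- txs[[ti]]; ii <- info[[ti]]
    emap <- tx_exon_map(tx)
    u5_len <- match(ii$map[1L], emap) - 1L
    cds_len <- 3L * ii$k
    total <- length(emap)
    rng <- if (five) seq_len(u5_len) - 1L
           else seq.int(u5_len + cds_len, total - 1L)
    if (!length(rng)) return(FALSE)
    rng <- rng[order(abs(rng - stats::median(rng)))]   # middle outwards
    cls <- if (five) "utr5_snv" else "utr3_snv"
    exp <- if (five) c("UTR5", "5_prime_UTR_variant")
           else c("UTR3", "3_prime_UTR_variant")
    for (tpos in rng) {
      g <- emap[tpos + 1L]
      if (dist_junction(tx, g) <= 8L) next
      ref <- genome_fetch(genome, chrom, g, g + 1L)
      if (add_variant(cls, g, ref, setdiff(BASES, ref)[1L],
                      tx$transcript_id, exp[1L], exp[2L])) return(TRUE)
    }
    FALSE
  }

  spans <- t(vapply(sim$set_b$transcripts, tx_span, integer(2L)))
  place_intergenic <- function(inst) {
    for (i in seq_len(nrow(sim$gaps))) {
      gs <- sim$gaps[i, 1L]; ge <- sim$gaps[i, 2L]
      mid <- gs + (ge - gs) %/% 2L
      for (g in mid + c(0L, 7L, -7L, 14L, -14L, 21L, -21L)) {
        if (g <= gs || g >= ge) next
        d <- min(pmax(spans[, 1L] - g - 1L, g - spans[, 2L]))
        if (d < 1002L) next
        ref <- genome_fetch(genome, chrom, g, g + 1L)
        if (add_variant("intergenic_snv", g, ref, setdiff(BASES, ref)[1L],
                        NA_character_, "intergenic", "intergenic_variant"))
          return(TRUE)
      }
    }
    FALSE
  }

  for (class in names(class_mix)) {
    n <- class_mix[[class]]
    for (inst in seq_len(n)) {
      ok <- if (class == "intergenic_snv") place_intergenic(inst)
            else place_one(class, inst)
      if (!ok)
        stop("could not place designed class '", class, "' (instance ",
             inst, "): no feasible candidate position")
    }
  }
  variants <- do.call(rbind, vars)
  truth <- do.call(rbind, truth)
  rownames(variants) <- rownames(truth) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(variants, genome, file.path(outdir, "variants.vcf"))
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(variants = variants, truth = truth)
}

#' Build the transcript-set discordance scenario
#'
#' The full designed-variant mix over the shared genes, plus one missense
#' and one stop-gain variant inside each set-B-only gene. Those extra
#' variants are exonic under set B and intergenic under set A (gaps exceed
#' twice the flank), so annotating both sides with the same regime
#' reproduces the transcript-set asymmetry at small scale with a closed-form
#' expected exonic match rate.
#'
#' @param config [sim_config()]; must have `extra_transcript_fraction > 0`.
#' @return list: `sim`, `variants`, `truth`, `bonly_variant_ids`, `regime`
#'   (the shared A_style regime) and `expected` — closed-form
#'   `n_exonic_both`, `n_exonic_either`, `overall_exonic_match_rate` and
#'   `n_bonly_variants`.
#' @export
make_discordance_scenario <- function(config = sim_config()) {
  sim <- simulate_genome_and_transcripts(config)
  vt <- simulate_variants(sim)
  bonly_ids <- setdiff(names(sim$set_b$transcripts),
                       names(sim$set_a$transcripts))
  extra_mix <- if (length(bonly_ids))
    stats::setNames(rep(0L, 16L), names(sim$config$class_mix)) else NULL
  bvars <- list(); btruth <- list()
  genome <- sim$genome
  tab <- codon_table()
  used_keys <- paste(vt$variants$pos, vt$variants$ref, vt$variants$alt)
  bi <- 0L
  for (id in sort(bonly_ids)) {
    tx <- sim$set_b$transcripts[[id]]
    ii <- tx_cds_info(tx, genome)
    codons <- split_codons(ii$cds)
    for (want in c("missense", "stopgain")) {
      placed <- FALSE
      for (ci in seq.int(1L, ii$k - 2L)) {
        if (placed) break
        rc <- codons[ci + 1L]
        for (j in 0:2) {
          if (placed) break
          t <- 3L * ci + j
          g <- ii$map[t + 1L]
          if (dist_junction(tx, g) <= 8L) next
          for (b in c("A", "C", "G", "T")) {
            ac <- rc
            substr(ac, j + 1L, j + 1L) <- b
            if (ac == rc) next
            ok_class <- if (want == "missense")
              !(ac %in% STOP_CODONS) && tab[[rc]] != tab[[ac]]
            else ac %in% STOP_CODONS
            if (!ok_class) next
            rec <- snv_record(genome, tx, g, b)
            if (is.null(rec)) next
            key <- paste(rec$pos, rec$ref, rec$alt)
            if (key %in% used_keys) next
            used_keys <- c(used_keys, key)
            bi <- bi + 1L
            vid <- sprintf("b%03d_%s_bonly", bi, want)
            bvars[[bi]] <- variant_df(vid, sim$config$chrom, rec$pos,
                                      rec$ref, rec$alt)
            bterm <- if (want == "missense") "nonsynonymous_SNV"
                     else "stopgain_SNV"
            btruth[[bi]] <- data.frame(
              variant_id = vid, class = paste0(want, "_bonly"),
              chrom = sim$config$chrom, pos = rec$pos, ref = rec$ref,
              alt = rec$alt, target_transcript = id,
              expected_a = bterm, expected_v = bterm,
              category_a = term_category(bterm, "A_style"),
              category_v = term_category(bterm, "A_style"),
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed)
        stop("could not place ", want, " variant in B-only transcript ", id)
    }
  }
  variants <- rbind(vt$variants, do.call(rbind, bvars))
  truth <- rbind(vt$truth, do.call(rbind, btruth))
  exonic_classes <- c("stop_loss_snv", "stop_retained_insertion",
                      "stop_gain_snv", "frameshift_indel", "inframe_indel",
                      "missense_snv", "synonymous_snv", "splice_donor_snv",
                      "splice_acceptor_snv", "splice_region_snv",
                      "initiator_codon_snv", "stopgain_via_indel")
  n_both <- sum(vt$truth$class %in% exonic_classes)
  n_bonly <- length(bvars)
  list(sim = sim, variants = variants, truth = truth,
       bonly_variant_ids = vapply(bvars, function(v) v$variant_id, ""),
       regime = a_style_regime(),
       expected = list(
         n_exonic_both = n_both,
         n_exonic_either = n_both + n_bonly,
         n_bonly_variants = n_bonly,
         overall_exonic_match_rate =
           if (n_both + n_bonly > 0) 100 * n_both / (n_both + n_bonly)
           else NA_real_))
}
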