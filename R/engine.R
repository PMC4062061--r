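# The consequence engine: classify each (variant, transcript) pair under a
# regime, then select the reported annotation per variant.
#
# A variant's genomic footprint is [pos, pos + nchar(ref)); a pure insertion
# has a zero-width footprint that associates with the base to its left
# (insert-after-base semantics, stable under left-alignment).

footprint <- function(v) c(s = v$pos, e = v$pos + nchar(v$ref))

## ---- location ----------------------------------------------------------

#' Locate a variant relative to one transcript
#'
#' Pure interval arithmetic, regime-free: where does the footprint fall?
#' Strand-aware for the 5'/3' labels. Variants spanning an exon/intron
#' junction report `splice_site_candidate`; the regime-dependent splicing
#' and coding rules live in [classify_splicing()] and [classify_coding()].
#'
#' @param variant one-row variant data.frame (see [read_variants()]).
#' @param tx `vc_transcript`.
#' @param flank_bp flank width for upstream/downstream calls.
#' @return one of `cds_exonic`, `utr5`, `utr3`, `intronic`,
#'   `splice_site_candidate`, `nc_exonic`, `nc_intronic`, `upstream`,
#'   `downstream`, `outside`.
#' @export
locate_variant <- function(variant, tx, flank_bp = 1000L) {
  stopifnot(variant$chrom == tx$chrom)
  fp <- footprint(variant)
  sp <- tx_span(tx)
  if (!overlaps_iv(fp["s"], fp["e"], sp[1L], sp[2L])) {
    left <- fp["e"] <= sp[1L]
    d <- if (left) sp[1L] - fp["e"] else fp["s"] - sp[2L]
    if (d >= flank_bp) return("outside")
    if (left) return(if (tx$strand == "+") "upstream" else "downstream")
    return(if (tx$strand == "+") "downstream" else "upstream")
  }
  ov_ex <- any(apply(tx$exons, 1L, function(iv)
    overlaps_iv(fp["s"], fp["e"], iv[1L], iv[2L])))
  introns <- tx_introns(tx)
  ov_in <- nrow(introns) > 0L && any(apply(introns, 1L, function(iv)
    overlaps_iv(fp["s"], fp["e"], iv[1L], iv[2L])))
  if (ov_ex && ov_in) return("splice_site_candidate")
  if (!ov_ex) return(if (tx$biotype == "coding") "intronic" else "nc_intronic")
  if (tx$biotype != "coding") return("nc_exonic")
  ov_cds <- any(apply(tx$cds, 1L, function(iv)
    overlaps_iv(fp["s"], fp["e"], iv[1L], iv[2L])))
  if (ov_cds) return("cds_exonic")
  cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
  left_of_cds <- if (fp["s"] == fp["e"]) fp["s"] <= cds_lo else fp["e"] <= cds_lo
  if (left_of_cds) return(if (tx$strand == "+") "utr5" else "utr3")
  if (tx$strand == "+") "utr3" else "utr5"
}

## ---- splicing ----------------------------------------------------------

#' Classify a variant against a transcript's splice junctions
#'
#' A_style: one broad `splicing` term for any variant within
#' `splicing_window_bp` intronic bases of a junction (optionally also the
#' exonic side, `window_side = "both"`). V_style: `splice_donor_variant`
#' (the two intronic bases at the 5' end of an intron, strand-aware),
#' `splice_acceptor_variant` (two bases at the 3' end), and
#' `splice_region_variant` (exonic 1-3 bp or intronic 3-8 bp from the
#' junction). Returns `NULL` when no splicing definition is hit; single-exon
#' transcripts have no splice sites.
#'
#' @param variant one-row variant data.frame.
#' @param tx `vc_transcript`.
#' @param regime `vc_regime`.
#' @return `NULL`, or a list with `term`, `distance_bp` (1-based distance to
#'   the nearest hit junction) and `side` (`"exonic"`/`"intronic"`).
#' @export
classify_splicing <- function(variant, tx, regime) {
  introns <- tx_introns(tx)
  if (!nrow(introns)) return(NULL)
  fp <- footprint(variant)
  hit <- function(a, b) {
    b <- max(a, b)
    a >= b && return(FALSE)
    overlaps_iv(fp["s"], fp["e"], a, b)
  }
  # 1-based distance from footprint to junction boundary j (junction sits
  # between base j-1 and base j)
  dist_to <- function(j) {
    ds <- abs(c(fp["s"] - j, fp["e"] - 1L - j, fp["e"] - j))
    min(ds) + 1L
  }
  best <- NULL
  take <- function(term, prio, j, side) {
    cand <- list(term = term, prio = prio, distance_bp = dist_to(j), side = side)
    if (is.null(best) || cand$prio < best$prio ||
        (cand$prio == best$prio && cand$distance_bp < best$distance_bp))
      best <<- cand
  }
  w <- regime$splicing_window_bp
  dl <- regime$splice_donor_len; al <- regime$splice_acceptor_len
  er <- regime$splice_region_exonic_bp; ir <- regime$splice_region_intronic_bp
  for (i in seq_len(nrow(introns))) {
    is_ <- introns[i, 1L]; ie <- introns[i, 2L]
    if (regime$vocabulary == "A_style") {
      if (w > 0L && (hit(is_, min(is_ + w, ie)) || hit(max(ie - w, is_), ie)))
        take("splicing", 1L, if (hit(is_, min(is_ + w, ie))) is_ else ie, "intronic")
      if (regime$window_side == "both" && w > 0L &&
          (hit(is_ - w, is_) || hit(ie, ie + w)))
        take("splicing", 1L, if (hit(is_ - w, is_)) is_ else ie, "exonic")
    } else {
      donor_iv <- if (tx$strand == "+") c(is_, min(is_ + dl, ie))
                  else c(max(ie - dl, is_), ie)
      acc_iv <- if (tx$strand == "+") c(max(ie - al, is_), ie)
                else c(is_, min(is_ + al, ie))
      if (hit(donor_iv[1L], donor_iv[2L]))
        take("splice_donor_variant", 1L,
             if (tx$strand == "+") is_ else ie, "intronic")
      if (hit(acc_iv[1L], acc_iv[2L]))
        take("splice_acceptor_variant", 2L,
             if (tx$strand == "+") ie else is_, "intronic")
      # splice region: strand-symmetric distances
      if (hit(is_ + ir[1L] - 1L, min(is_ + ir[2L], ie)))
        take("splice_region_variant", 3L, is_, "intronic")
      if (hit(max(ie - ir[2L], is_), ie - ir[1L] + 1L))
        take("splice_region_variant", 3L, ie, "intronic")
      if (hit(is_ - er[2L], is_ - er[1L] + 1L))
        take("splice_region_variant", 3L, is_, "exonic")
      if (hit(ie + er[1L] - 1L, ie + er[2L]))
        take("splice_region_variant", 3L, ie, "exonic")
    }
  }
  if (is.null(best)) NULL
  else best[c("term", "distance_bp", "side")]
}

## ---- coding ------------------------------------------------------------

# genomic-order concatenated CDS string and the concat offset of a genomic
# position within it
cds_concat <- function(tx, genome) {
  paste(vapply(seq_len(nrow(tx$cds)), function(i)
    genome_fetch(genome, tx$chrom, tx$cds[i, 1L], tx$cds[i, 2L]), ""),
    collapse = "")
}

cds_offset <- function(tx, gpos) {
  off <- 0L
  for (i in seq_len(nrow(tx$cds))) {
    a <- tx$cds[i, 1L]; b <- tx$cds[i, 2L]
    if (gpos >= a && gpos <= b) return(off + (gpos - a))
    off <- off + (b - a)
  }
  NA_integer_
}

#' Classify a coding-sequence variant
#'
#' Rebuilds the spliced CDS (reverse-complemented for minus-strand
#' transcripts), applies the variant, re-translates, and classifies by
#' comparing the reference and alternate proteins. Implements the regime's
#' stop-retained demotion (a variant leaving a stop codon at the same
#' protein position is synonymous/stop-retained, never frameshift or
#' stop-loss) and the A_style indel stop-scan (premature stop in the
#' re-translated frame is reported stop-gain rather than frameshift).
#'
#' @param variant one-row variant data.frame whose footprint lies inside a
#'   single CDS interval of `tx`.
#' @param tx coding `vc_transcript`.
#' @param genome `vc_genome`.
#' @param regime `vc_regime`.
#' @return list with `term` plus detail fields (`ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `protein_pos`, `low_confidence`).
#' @export
classify_coding <- function(variant, tx, genome, regime) {
  stopifnot(tx$biotype == "coding")
  vocab <- regime$vocabulary
  fp <- footprint(variant)
  diff <- nchar(variant$alt) - nchar(variant$ref)
  concat <- cds_concat(tx, genome)
  L <- nchar(concat)
  off <- cds_offset(tx, fp[["s"]])
  if (is.na(off)) stop("variant footprint not inside CDS: ", variant$variant_id)
  alt_concat <- paste0(substr(concat, 1L, off), variant$alt,
                       substr(concat, off + nchar(variant$ref) + 1L, L))
  minus <- tx$strand == "-"
  ref_cds <- if (minus) revcomp(concat) else concat
  alt_cds <- if (minus) revcomp(alt_concat) else alt_concat
  La <- nchar(alt_cds)
  # translation-orientation coordinates of the edit
  t0 <- if (minus) L - (off + max(nchar(variant$ref), 1L)) else off
  t1 <- t0 + max(nchar(variant$ref), 1L)      # [t0, t1) in ref CDS
  overlaps_start <- overlaps_iv(t0, if (fp[["s"]] == fp[["e"]]) t0 else t1,
                                0L, 3L)
  overlaps_stop <- overlaps_iv(t0, if (fp[["s"]] == fp[["e"]]) t0 else t1,
                               L - 3L, L)
  low_conf <- isTRUE(tx$cds_incomplete)

  detail <- function(term, ref_codon = NA, alt_codon = NA, ref_aa = NA,
                     alt_aa = NA, protein_pos = NA)
    list(term = term, ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa, protein_pos = protein_pos,
         low_confidence = low_conf)

  # N-containing codons near the edit make the call indeterminate
  c0 <- max(0L, (t0 %/% 3L) - 1L)
  c1 <- min(L %/% 3L, (t1 %/% 3L) + 2L)
  near_ref <- substr(ref_cds, c0 * 3L + 1L, c1 * 3L)
  near_alt <- substr(alt_cds, c0 * 3L + 1L, min(La, (c1 + 2L) * 3L))
  if (grepl("N", near_ref) || grepl("N", near_alt) ||
      grepl("N", variant$alt))
    return(detail("unknown"))

  aa_ref <- translate_codons(ref_cds)
  aa_alt <- translate_codons(alt_cds)
  ref_stop <- match("*", aa_ref)
  alt_stop <- match("*", aa_alt)

  term2 <- function(a, v) if (vocab == "A_style") a else v

  # stop-retained / protein-preserving check
  same_protein <- !is.na(ref_stop) && !is.na(alt_stop) &&
    alt_stop == ref_stop &&
    identical(aa_ref[seq_len(ref_stop - 1L)], aa_alt[seq_len(alt_stop - 1L)])
  if (regime$stop_retained_detection && same_protein) {
    if (overlaps_stop)
      return(detail(term2("synonymous_SNV", "stop_retained_variant"),
                    protein_pos = ref_stop))
    if (diff == 0L && variant$var_class == "SNV") {
      ci <- t0 %/% 3L
      return(detail(term2("synonymous_SNV", "synonymous_variant"),
                    ref_codon = split_codons(ref_cds)[ci + 1L],
                    alt_codon = split_codons(alt_cds)[ci + 1L],
                    ref_aa = aa_ref[ci + 1L], alt_aa = aa_alt[ci + 1L],
                    protein_pos = ci + 1L))
    }
    return(detail(term2("synonymous_SNV", "stop_retained_variant")))
  }

  if (diff %% 3L != 0L) {
    premature <- !is.na(alt_stop) && alt_stop < length(aa_alt)
    if (regime$stop_scan_indels && premature)
      return(detail(term2("stopgain_SNV", "stop_gained"),
                    protein_pos = alt_stop))
    a_term <- switch(variant$var_class,
                     insertion = "frameshift_insertion",
                     deletion = "frameshift_deletion",
                     "frameshift_substitution")
    return(detail(term2(a_term, "frameshift_variant")))
  }

  if (variant$var_class == "SNV") {
    ci <- t0 %/% 3L
    rc <- split_codons(ref_cds)[ci + 1L]
    ac <- split_codons(alt_cds)[ci + 1L]
    ra <- aa_ref[ci + 1L]; aa <- aa_alt[ci + 1L]
    d <- detail("placeholder", ref_codon = rc, alt_codon = ac, ref_aa = ra,
                alt_aa = aa, protein_pos = ci + 1L)
    d$term <-
      if (ci == 0L && rc == "ATG" && ac != "ATG")
        term2("nonsynonymous_SNV", "initiator_codon_variant")
      else if (!is.na(ra) && ra == "*" && !is.na(aa) && aa == "*")
        term2("synonymous_SNV", "stop_retained_variant")
      else if (!is.na(ra) && ra == "*")
        term2("stoploss_SNV", "stop_lost")
      else if (!is.na(aa) && aa == "*")
        term2("stopgain_SNV", "stop_gained")
      else if (identical(ra, aa))
        term2("synonymous_SNV", "synonymous_variant")
      else term2("nonsynonymous_SNV", "missense_variant")
    return(d)
  }

  # in-frame indel / block substitution
  if (overlaps_stop)
    return(detail(term2("stoploss_SNV", "stop_lost")))
  expected_stop <- if (!is.na(ref_stop)) ref_stop + diff %/% 3L else NA
  premature <- !is.na(alt_stop) &&
    (is.na(expected_stop) || alt_stop < expected_stop)
  if (regime$stop_scan_indels && premature)
    return(detail(term2("stopgain_SNV", "stop_gained"), protein_pos = alt_stop))
  if (overlaps_start)
    return(detail(term2("nonsynonymous_SNV", "initiator_codon_variant"),
                  protein_pos = 1L))
  if (diff > 0L) {
    a_term <- if (variant$var_class == "insertion") "nonframeshift_insertion"
              else "nonframeshift_substitution"
    return(detail(term2(a_term, "inframe_insertion")))
  }
  if (diff < 0L) {
    a_term <- if (variant$var_class == "deletion") "nonframeshift_deletion"
              else "nonframeshift_substitution"
    return(detail(term2(a_term, "inframe_deletion")))
  }
  # equal-length block substitution
  if (identical(aa_ref, aa_alt))
    return(detail(term2("synonymous_SNV", "synonymous_variant")))
  detail(term2("nonframeshift_substitution", "missense_variant"))
}

## ---- per-transcript and per-variant annotation -------------------------

empty_call <- function() data.frame(
  variant_id = character(0), term = character(0),
  transcript_id = character(0), gene_id = character(0),
  ref_codon = character(0), alt_codon = character(0),
  ref_aa = character(0), alt_aa = character(0),
  protein_pos = integer(0), distance_bp = integer(0), side = character(0),
  low_confidence = logical(0), stringsAsFactors = FALSE)

call_row <- function(variant, term, tx = NULL, detail = list()) {
  data.frame(
    variant_id = variant$variant_id, term = term,
    transcript_id = if (is.null(tx)) NA_character_ else tx$transcript_id,
    gene_id = if (is.null(tx)) NA_character_ else tx$gene_id,
    ref_codon = as.character(detail$ref_codon %||% NA),
    alt_codon = as.character(detail$alt_codon %||% NA),
    ref_aa = as.character(detail$ref_aa %||% NA),
    alt_aa = as.character(detail$alt_aa %||% NA),
    protein_pos = as.integer(detail$protein_pos %||% NA),
    distance_bp = as.integer(detail$distance_bp %||% NA),
    side = as.character(detail$side %||% NA),
    low_confidence = isTRUE(detail$low_confidence),
    stringsAsFactors = FALSE)
}

utr_side_term <- function(variant, tx, vocab) {
  fp <- footprint(variant)
  cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
  left <- if (fp["s"] == fp["e"]) fp["s"] <= cds_lo else fp["e"] <= cds_lo
  five <- (left && tx$strand == "+") || (!left && tx$strand == "-")
  if (vocab == "A_style") {
    if (five) "UTR5" else "UTR3"
  } else {
    if (five) "5_prime_UTR_variant" else "3_prime_UTR_variant"
  }
}

# all calls for one (variant, transcript) pair under a regime
annotate_transcript <- function(variant, tx, genome, regime) {
  vocab <- regime$vocabulary
  fp <- footprint(variant)
  sp <- tx_span(tx)
  if (!overlaps_iv(fp["s"], fp["e"], sp[1L], sp[2L])) {
    left <- fp["e"] <= sp[1L]
    d <- if (left) sp[1L] - fp["e"] else fp["s"] - sp[2L]
    if (d >= regime$flank_bp) return(empty_call())
    up <- (left && tx$strand == "+") || (!left && tx$strand == "-")
    term <- if (vocab == "A_style") {
      if (up) "upstream" else "downstream"
    } else {
      if (up) "upstream_gene_variant" else "downstream_gene_variant"
    }
    return(call_row(variant, term, tx, list(distance_bp = d + 1L)))
  }
  splice <- classify_splicing(variant, tx, regime)
  ov <- function(iv) overlaps_iv(fp["s"], fp["e"], iv[1L], iv[2L])
  ov_exon <- any(apply(tx$exons, 1L, ov))
  introns <- tx_introns(tx)
  ov_intron <- nrow(introns) > 0L && any(apply(introns, 1L, ov))

  if (tx$biotype != "coding") {
    term <- if (!is.null(splice)) {
      if (vocab == "A_style") "ncRNA_splicing"
      else "non_coding_transcript_splice_variant"
    } else if (ov_exon) {
      if (vocab == "A_style") "ncRNA_exonic" else "non_coding_exon_variant"
    } else {
      if (vocab == "A_style") "ncRNA_intronic" else "non_coding_intron_variant"
    }
    det <- if (!is.null(splice)) splice[c("distance_bp", "side")] else list()
    return(call_row(variant, term, tx, det))
  }

  ov_cds <- any(apply(tx$cds, 1L, ov))
  in_cds <- any(apply(tx$cds, 1L, function(iv)
    contained_iv(fp["s"], fp["e"], iv[1L], iv[2L])))

  if (vocab == "A_style") {
    if (!is.null(splice))
      return(call_row(variant, "splicing", tx,
                      splice[c("distance_bp", "side")]))
    if (in_cds) {
      cc <- classify_coding(variant, tx, genome, regime)
      return(call_row(variant, cc$term, tx, cc))
    }
    if (ov_cds) {
      diff <- nchar(variant$alt) - nchar(variant$ref)
      cls <- variant$var_class
      term <- if (diff %% 3L != 0L)
        switch(cls, insertion = "frameshift_insertion",
               deletion = "frameshift_deletion", "frameshift_substitution")
      else switch(cls, insertion = "nonframeshift_insertion",
                  deletion = "nonframeshift_deletion",
                  "nonframeshift_substitution")
      return(call_row(variant, term, tx, list(low_confidence = TRUE)))
    }
    if (ov_exon && !ov_intron)
      return(call_row(variant, utr_side_term(variant, tx, vocab), tx))
    return(call_row(variant, "intronic", tx))
  }

  # V_style: splice call (if any) plus a location/coding call; a purely
  # intronic splice hit stands alone, severity selection resolves the rest.
  calls <- empty_call()
  if (!is.null(splice))
    calls <- rbind(calls, call_row(variant, splice$term, tx,
                                   splice[c("distance_bp", "side")]))
  add_location <- is.null(splice) || ov_exon
  if (add_location) {
    loc_call <- if (in_cds) {
      cc <- classify_coding(variant, tx, genome, regime)
      call_row(variant, cc$term, tx, cc)
    } else if (ov_cds) {
      call_row(variant, "coding_sequence_variant", tx,
               list(low_confidence = TRUE))
    } else if (ov_exon && !ov_intron) {
      call_row(variant, utr_side_term(variant, tx, vocab), tx)
    } else {
      call_row(variant, "intron_variant", tx)
    }
    calls <- rbind(calls, loc_call)
  }
  calls
}

#' Annotate variants against a transcript set
#'
#' Produces per-transcript consequence calls for every transcript
#' overlapping each variant (plus upstream/downstream transcripts within the
#' regime's flank; `intergenic` when there are none) and applies the
#' regime's reporting policy: `most_severe_only` keeps exactly one call per
#' variant (severity ranking, ties broken by transcript id);
#' `all_then_prioritise` keeps all calls and marks the primary.
#'
#' @param variants variant data.frame (see [read_variants()]).
#' @param tset `vc_transcript_set`.
#' @param genome `vc_genome`.
#' @param regime `vc_regime`.
#' @param ranking optional [severity_ranking()]; defaults to the regime
#'   vocabulary's shipped ranking.
#' @return data.frame of consequence calls: variant fields, `term`,
#'   `transcript_id`, `gene_id`, codon/protein detail columns and `primary`.
#' @export
annotate_variants <- function(variants, tset, genome, regime,
                              ranking = NULL) {
  if (is.null(ranking)) ranking <- severity_ranking(regime$vocabulary)
  stopifnot(ranking$vocabulary == regime$vocabulary)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    fp <- footprint(v)
    qs <- if (fp["s"] == fp["e"]) max(0L, fp["s"] - 1L) else fp["s"]
    ids <- transcripts_at(tset, v$chrom, qs, max(fp["e"], fp["s"] + 1L),
                          flank_bp = regime$flank_bp)
    calls <- empty_call()
    for (id in ids) {
      tx <- tset$transcripts[[id]]
      if (tx$chrom != v$chrom) next
      calls <- rbind(calls, annotate_transcript(v, tx, genome, regime))
    }
    if (!nrow(calls)) {
      term <- if (regime$vocabulary == "A_style") "intergenic"
              else "intergenic_variant"
      calls <- call_row(v, term)
    }
    if (regime$report_policy == "most_severe_only") {
      calls <- most_severe(calls, ranking)
      calls$primary <- TRUE
    } else {
      pick <- most_severe(calls, ranking)
      is_pick <- calls$term == pick$term &
        (is.na(calls$transcript_id) == is.na(pick$transcript_id)) &
        (is.na(calls$transcript_id) | calls$transcript_id ==
           (pick$transcript_id %||% NA_character_))
      calls$primary <- FALSE
      calls$primary[which(is_pick)[1L]] <- TRUE
    }
    vcols <- v[, c("chrom", "pos", "ref", "alt", "var_class")]
    rownames(vcols) <- NULL
    out[[i]] <- cbind(calls, vcols[rep(1L, nrow(calls)), , drop = FALSE])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
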