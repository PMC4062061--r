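# Harmonization of the two vocabularies: high-level categories, report
# rollup groups and the cross-vocabulary exact-equivalence map.
#
# Two distinct maps, both needed to reproduce the published accounting:
#   * category_map(): the methods-level categories used for CATEGORY
#     matching. General splice-region variants sit at missense level here;
#     donor/acceptor and the broad A_style splicing term are LoF.
#   * rollup_group(): the grouping used for report rows, where ALL splicing
#     subterms are tabulated under LoF (the broad tool vocabulary has no
#     splicing subcategories, so its comparison rows keep the three fine
#     splice terms together).

CATEGORY_LEVELS <- c("LOF", "MISSENSE", "SYNONYMOUS_OTHER", "UTR", "NCRNA",
                     "INTRONIC", "INTERGENIC_FLANK", "UNKNOWN")

A_STYLE_CATEGORY <- c(
  stopgain_SNV = "LOF", stoploss_SNV = "LOF", splicing = "LOF",
  frameshift_insertion = "LOF", frameshift_deletion = "LOF",
  frameshift_substitution = "LOF",
  nonsynonymous_SNV = "MISSENSE",
  nonframeshift_insertion = "MISSENSE", nonframeshift_deletion = "MISSENSE",
  nonframeshift_substitution = "MISSENSE",
  synonymous_SNV = "SYNONYMOUS_OTHER",
  UTR5 = "UTR", UTR3 = "UTR",
  ncRNA_splicing = "NCRNA", ncRNA_exonic = "NCRNA", ncRNA_intronic = "NCRNA",
  intronic = "INTRONIC",
  upstream = "INTERGENIC_FLANK", downstream = "INTERGENIC_FLANK",
  intergenic = "INTERGENIC_FLANK",
  unknown = "UNKNOWN"
)

V_STYLE_CATEGORY <- c(
  stop_gained = "LOF", stop_lost = "LOF", frameshift_variant = "LOF",
  splice_donor_variant = "LOF", splice_acceptor_variant = "LOF",
  missense_variant = "MISSENSE", initiator_codon_variant = "MISSENSE",
  inframe_insertion = "MISSENSE", inframe_deletion = "MISSENSE",
  splice_region_variant = "MISSENSE",
  synonymous_variant = "SYNONYMOUS_OTHER",
  stop_retained_variant = "SYNONYMOUS_OTHER",
  coding_sequence_variant = "SYNONYMOUS_OTHER",
  `5_prime_UTR_variant` = "UTR", `3_prime_UTR_variant` = "UTR",
  non_coding_transcript_splice_variant = "NCRNA",
  non_coding_exon_variant = "NCRNA", non_coding_intron_variant = "NCRNA",
  intron_variant = "INTRONIC",
  upstream_gene_variant = "INTERGENIC_FLANK",
  downstream_gene_variant = "INTERGENIC_FLANK",
  intergenic_variant = "INTERGENIC_FLANK",
  unknown = "UNKNOWN"
)

# exact cross-vocabulary equivalents, A_style term -> V_style term(s).
# The broad "splicing" term is exact-equivalent to all three fine splice
# terms; initiator-codon, stop-retained and coding_sequence (other coding)
# have no A_style equivalent, so their exact-match count against an A_style
# run is structurally zero. "unknown" matches nothing, not even itself,
# across vocabularies.
EQUIVALENCE_A_TO_V <- list(
  stopgain_SNV = "stop_gained",
  stoploss_SNV = "stop_lost",
  frameshift_insertion = "frameshift_variant",
  frameshift_deletion = "frameshift_variant",
  frameshift_substitution = "frameshift_variant",
  splicing = c("splice_donor_variant", "splice_acceptor_variant",
               "splice_region_variant"),
  nonsynonymous_SNV = "missense_variant",
  nonframeshift_insertion = "inframe_insertion",
  nonframeshift_deletion = "inframe_deletion",
  nonframeshift_substitution = c("inframe_insertion", "inframe_deletion"),
  synonymous_SNV = "synonymous_variant",
  UTR5 = "5_prime_UTR_variant",
  UTR3 = "3_prime_UTR_variant",
  ncRNA_splicing = "non_coding_transcript_splice_variant",
  ncRNA_exonic = "non_coding_exon_variant",
  ncRNA_intronic = "non_coding_intron_variant",
  intronic = "intron_variant",
  upstream = "upstream_gene_variant",
  downstream = "downstream_gene_variant",
  intergenic = "intergenic_variant"
)

#' High-level category of every term of a vocabulary
#'
#' @param vocabulary `"A_style"` or `"V_style"`.
#' @return named character vector term -> category (one of `LOF`,
#'   `MISSENSE`, `SYNONYMOUS_OTHER`, `UTR`, `NCRNA`, `INTRONIC`,
#'   `INTERGENIC_FLANK`, `UNKNOWN`).
#' @export
category_map <- function(vocabulary = c("A_style", "V_style")) {
  switch(match.arg(vocabulary),
         A_style = A_STYLE_CATEGORY, V_style = V_STYLE_CATEGORY)
}

#' @rdname category_map
#' @param term consequence term (scalar or vector).
#' @export
term_category <- function(term, vocabulary) {
  cm <- category_map(vocabulary)
  out <- unname(cm[term])
  if (anyNA(out))
    stop("term(s) not in ", vocabulary, " vocabulary: ",
         paste(unique(term[is.na(out)]), collapse = ", "))
  out
}

#' Report rollup group of a consequence term
#'
#' The grouping used for report rollup rows. Identical to [term_category()]
#' except that `splice_region_variant` is tabulated with the other splicing
#' terms under `LOF`, matching how comparison tables keep all splicing
#' subterms together while category matching treats general splice-region
#' variants as missense-level.
#'
#' @inheritParams term_category
#' @return character vector of group labels.
#' @export
rollup_group <- function(term, vocabulary) {
  g <- term_category(term, vocabulary)
  g[term == "splice_region_variant"] <- "LOF"
  g
}

# equivalence-family label for fine report rows of a cross-vocabulary
# comparison (Frameshift, All splicing, Inframe indel, ...). Same-vocabulary
# comparisons use the term itself as its family.
TERM_FAMILY_A <- c(
  stopgain_SNV = "stop_gained", stoploss_SNV = "stop_lost",
  frameshift_insertion = "frameshift", frameshift_deletion = "frameshift",
  frameshift_substitution = "frameshift",
  splicing = "all_splicing",
  nonsynonymous_SNV = "missense",
  nonframeshift_insertion = "inframe_indel",
  nonframeshift_deletion = "inframe_indel",
  nonframeshift_substitution = "inframe_indel",
  synonymous_SNV = "synonymous",
  UTR5 = "UTR5", UTR3 = "UTR3",
  ncRNA_splicing = "ncRNA_splicing", ncRNA_exonic = "ncRNA_exonic",
  ncRNA_intronic = "ncRNA_intronic",
  intronic = "intronic", upstream = "upstream", downstream = "downstream",
  intergenic = "intergenic", unknown = "unknown"
)

TERM_FAMILY_V <- c(
  stop_gained = "stop_gained", stop_lost = "stop_lost",
  frameshift_variant = "frameshift",
  splice_donor_variant = "all_splicing",
  splice_acceptor_variant = "all_splicing",
  splice_region_variant = "all_splicing",
  missense_variant = "missense", initiator_codon_variant = "initiator_codon",
  inframe_insertion = "inframe_indel", inframe_deletion = "inframe_indel",
  synonymous_variant = "synonymous",
  stop_retained_variant = "stop_retained",
  coding_sequence_variant = "other_coding",
  `5_prime_UTR_variant` = "UTR5", `3_prime_UTR_variant` = "UTR3",
  non_coding_transcript_splice_variant = "ncRNA_splicing",
  non_coding_exon_variant = "ncRNA_exonic",
  non_coding_intron_variant = "ncRNA_intronic",
  intron_variant = "intronic", upstream_gene_variant = "upstream",
  downstream_gene_variant = "downstream",
  intergenic_variant = "intergenic", unknown = "unknown"
)

term_family <- function(term, vocabulary, cross = TRUE) {
  if (!cross) return(term)
  fam <- if (vocabulary == "A_style") TERM_FAMILY_A else TERM_FAMILY_V
  out <- unname(fam[term])
  if (anyNA(out))
    stop("term(s) without family in ", vocabulary, ": ",
         paste(unique(term[is.na(out)]), collapse = ", "))
  out
}

#' Load a harmonization config (category + equivalence maps)
#'
#' Reads the YAML layout shipped at
#' `system.file("extdata", "harmonization.yaml", package = "varconcord")`
#' and validates it: every emittable term of both vocabularies must carry
#' exactly one category, and every equivalence target must be a valid
#' V_style term.
#'
#' @param path YAML file; defaults to the shipped config.
#' @return list with `category` (per-vocabulary named vectors) and
#'   `equivalence` (A_style term -> V_style terms).
#' @export
load_harmonization <- function(path = system.file("extdata",
                                                  "harmonization.yaml",
                                                  package = "varconcord")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$category) || is.null(cfg$equivalence))
    stop("harmonization config needs 'category' and 'equivalence': ", path)
  out <- list(category = lapply(cfg$category, function(m)
    stats::setNames(unlist(m), names(m))), equivalence = cfg$equivalence)
  for (voc in c("A_style", "V_style")) {
    m <- out$category[[voc]]
    miss <- setdiff(vocabulary_terms(voc), names(m))
    if (length(miss))
      stop("harmonization config misses ", voc, " term(s): ",
           paste(miss, collapse = ", "))
    bad <- setdiff(unname(m), CATEGORY_LEVELS)
    if (length(bad))
      stop("unknown category level(s): ", paste(bad, collapse = ", "))
  }
  bad_eq <- setdiff(unlist(out$equivalence), vocabulary_terms("V_style"))
  if (length(bad_eq))
    stop("equivalence targets outside V_style vocabulary: ",
         paste(bad_eq, collapse = ", "))
  out
}

#' Match type of a pair of consequence calls
#'
#' `exact` when the two terms are (cross-vocabulary) equivalents — for two
#' runs sharing a vocabulary, plain term equality; `category` when not exact
#' but both terms fall in the same high-level category (`UNKNOWN` never
#' category-matches, not even itself); `mismatch` otherwise, including when
#' either side is absent. Exact matches count as category matches in all
#' report accounting, so exact implies category.
#'
#' @param term_a,term_b consequence terms (`NA` or `"absent"` for a variant
#'   unannotated in that run).
#' @param vocab_a,vocab_b the vocabulary of each run.
#' @return `"exact"`, `"category"` or `"mismatch"` (vectorized).
#' @export
match_type <- function(term_a, term_b, vocab_a, vocab_b) {
  n <- max(length(term_a), length(term_b))
  term_a <- rep_len(term_a, n); term_b <- rep_len(term_b, n)
  out <- rep("mismatch", n)
  present <- !is.na(term_a) & !is.na(term_b) &
    term_a != "absent" & term_b != "absent"
  if (!any(present)) return(out)
  ex <- logical(n)
  if (vocab_a == vocab_b) {
    ex[present] <- term_a[present] == term_b[present]
  } else {
    a <- if (vocab_a == "A_style") term_a else term_b
    v <- if (vocab_a == "A_style") term_b else term_a
    ex[present] <- mapply(function(at, vt) {
      eq <- EQUIVALENCE_A_TO_V[[at]]
      !is.null(eq) && vt %in% eq
    }, a[present], v[present])
  }
  cat_a <- rep(NA_character_, n); cat_b <- rep(NA_character_, n)
  cat_a[present] <- term_category(term_a[present], vocab_a)
  cat_b[present] <- term_category(term_b[present], vocab_b)
  same_cat <- present & cat_a == cat_b & cat_a != "UNKNOWN"
  out[same_cat] <- "category"
  out[ex] <- "exact"
  out
}
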