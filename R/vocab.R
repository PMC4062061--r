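# Consequence vocabularies and annotation regimes.
#
# Two definitional regimes are supported:
#   * A_style: a single broad "splicing" category (any variant within a
#     configurable number of intronic bases of an exon/intron junction),
#     indel stop-scanning (an indel whose re-translated CDS gains a premature
#     stop is reported stop-gain rather than frameshift), and historical
#     "_SNV"-suffixed stop terms.
#   * V_style: fine splicing subcategories (donor/acceptor = the two intronic
#     bases at either end of an intron; splice region = exonic 1-3 bp or
#     intronic 3-8 bp from a junction), no indel stop-scan, and dedicated
#     stop_retained / initiator-codon / coding_sequence terms that have no
#     A_style equivalent.

A_STYLE_TERMS <- c(
  "stopgain_SNV", "stoploss_SNV", "splicing",
  "frameshift_insertion", "frameshift_deletion", "frameshift_substitution",
  "nonsynonymous_SNV",
  "nonframeshift_insertion", "nonframeshift_deletion",
  "nonframeshift_substitution",
  "synonymous_SNV",
  "UTR5", "UTR3",
  "ncRNA_splicing", "ncRNA_exonic", "ncRNA_intronic",
  "intronic", "upstream", "downstream", "intergenic", "unknown"
)

V_STYLE_TERMS <- c(
  "stop_gained", "stop_lost", "frameshift_variant",
  "splice_donor_variant", "splice_acceptor_variant",
  "missense_variant", "initiator_codon_variant",
  "inframe_insertion", "inframe_deletion",
  "splice_region_variant",
  "synonymous_variant", "stop_retained_variant", "coding_sequence_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_splice_variant", "non_coding_exon_variant",
  "non_coding_intron_variant",
  "intron_variant", "upstream_gene_variant", "downstream_gene_variant",
  "intergenic_variant", "unknown"
)

#' Terms of a consequence vocabulary
#'
#' @param vocabulary `"A_style"` or `"V_style"`.
#' @return character vector of every term the engine can emit under that
#'   vocabulary.
#' @export
vocabulary_terms <- function(vocabulary) {
  switch(match.arg(vocabulary, c("A_style", "V_style")),
         A_style = A_STYLE_TERMS,
         V_style = V_STYLE_TERMS)
}

#' Construct an annotation regime
#'
#' A regime bundles every definitional choice that differs between
#' annotation tools: the term vocabulary, the splicing-window geometry, the
#' indel stop-scan and stop-retained rules, the upstream/downstream flank
#' width and the reporting policy. [a_style_regime()] and [v_style_regime()]
#' return the two shipped presets.
#'
#' @param name regime name.
#' @param vocabulary `"A_style"` or `"V_style"`.
#' @param splicing_window_bp intronic half-width (bp) of the broad A_style
#'   splicing window (the tool's user-settable x; 6 here).
#' @param window_side `"intronic_only"` (default) or `"both"`: whether the
#'   broad window also swallows exonic near-junction bases.
#' @param splice_donor_len,splice_acceptor_len lengths (bp) of the intronic
#'   donor/acceptor termini under V_style.
#' @param splice_region_exonic_bp,splice_region_intronic_bp inclusive
#'   distance ranges (bp from the junction) defining the V_style splice
#'   region on the exonic and intronic side.
#' @param stop_scan_indels logical: report an indel whose re-translated CDS
#'   gains a premature stop as stop-gain instead of frameshift.
#' @param stop_retained_detection logical: demote variants that leave the
#'   stop codon intact at the same protein position to
#'   synonymous/stop-retained.
#' @param flank_bp upstream/downstream flank width in bp.
#' @param report_policy `"most_severe_only"` or `"all_then_prioritise"`.
#' @return an object of class `vc_regime`.
#' @export
regime <- function(name,
                   vocabulary = c("A_style", "V_style"),
                   splicing_window_bp = 6L,
                   window_side = c("intronic_only", "both"),
                   splice_donor_len = 2L,
                   splice_acceptor_len = 2L,
                   splice_region_exonic_bp = c(1L, 3L),
                   splice_region_intronic_bp = c(3L, 8L),
                   stop_scan_indels = FALSE,
                   stop_retained_detection = TRUE,
                   flank_bp = 1000L,
                   report_policy = c("most_severe_only", "all_then_prioritise")) {
  vocabulary <- match.arg(vocabulary)
  window_side <- match.arg(window_side)
  report_policy <- match.arg(report_policy)
  stopifnot(splicing_window_bp >= 0L,
            splice_donor_len >= 1L, splice_acceptor_len >= 1L,
            flank_bp >= 0L,
            length(splice_region_exonic_bp) == 2L,
            length(splice_region_intronic_bp) == 2L)
  structure(list(
    name = name,
    vocabulary = vocabulary,
    splicing_window_bp = as.integer(splicing_window_bp),
    window_side = window_side,
    splice_donor_len = as.integer(splice_donor_len),
    splice_acceptor_len = as.integer(splice_acceptor_len),
    splice_region_exonic_bp = as.integer(splice_region_exonic_bp),
    splice_region_intronic_bp = as.integer(splice_region_intronic_bp),
    stop_scan_indels = isTRUE(stop_scan_indels),
    stop_retained_detection = isTRUE(stop_retained_detection),
    flank_bp = as.integer(flank_bp),
    report_policy = report_policy
  ), class = "vc_regime")
}

#' @rdname regime
#' @param ... overrides passed on to [regime()].
#' @export
a_style_regime <- function(...) {
  args <- list(...)
  defaults <- list(name = "a_style", vocabulary = "A_style",
                   splicing_window_bp = 6L, stop_scan_indels = TRUE,
                   stop_retained_detection = TRUE)
  do.call(regime, utils::modifyList(defaults, args))
}

#' @rdname regime
#' @export
v_style_regime <- function(...) {
  args <- list(...)
  defaults <- list(name = "v_style", vocabulary = "V_style",
                   stop_scan_indels = FALSE,
                   stop_retained_detection = TRUE)
  do.call(regime, utils::modifyList(defaults, args))
}

#' @export
print.vc_regime <- function(x, ...) {
  cat(sprintf("<vc_regime %s> vocabulary=%s window=%dbp(%s) donor/acceptor=%d/%dbp\n",
              x$name, x$vocabulary, x$splicing_window_bp, x$window_side,
              x$splice_donor_len, x$splice_acceptor_len))
  cat(sprintf("  stop_scan_indels=%s stop_retained=%s flank=%dbp policy=%s\n",
              x$stop_scan_indels, x$stop_retained_detection, x$flank_bp,
              x$report_policy))
  invisible(x)
}
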