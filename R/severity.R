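# Consequence-severity precedence: a total order over each vocabulary's
# terms, used to select the single reported annotation when several calls
# compete. The shipped defaults honour the orderings the underlying
# definitions imply (stop-gain above frameshift; donor/acceptor splicing in
# the LoF block; splice region at missense level); within-block order beyond
# that is one possible common-sense choice and fully config-overridable.

A_STYLE_SEVERITY <- c(
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

V_STYLE_SEVERITY <- c(
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

# category level used for ranking-consistency validation: LoF terms must all
# rank above missense-level terms, which rank above synonymous-level terms,
# which rank above everything non-exonic.
severity_level <- function(terms, vocabulary) {
  cm <- category_map(vocabulary)
  cat <- unname(cm[terms])
  lv <- rep(4L, length(terms))            # non-exonic
  lv[cat == "LOF"] <- 1L
  lv[cat == "MISSENSE"] <- 2L
  lv[cat == "SYNONYMOUS_OTHER"] <- 3L
  lv
}

#' Construct (and validate) a severity ranking
#'
#' @param vocabulary `"A_style"` or `"V_style"`.
#' @param terms ordered character vector, most severe first; defaults to the
#'   shipped ranking for the vocabulary. Must list every emittable term
#'   exactly once and keep the category blocks ordered (all LoF above all
#'   missense-level above all synonymous-level above all non-exonic terms).
#' @return object of class `vc_severity_ranking`.
#' @export
severity_ranking <- function(vocabulary = c("A_style", "V_style"),
                             terms = NULL) {
  vocabulary <- match.arg(vocabulary)
  if (is.null(terms))
    terms <- if (vocabulary == "A_style") A_STYLE_SEVERITY else V_STYLE_SEVERITY
  all_terms <- vocabulary_terms(vocabulary)
  dup <- terms[duplicated(terms)]
  if (length(dup))
    stop("duplicate term(s) in ranking: ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(all_terms, terms)
  if (length(missing))
    stop("ranking omits term(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(terms, all_terms)
  if (length(extra))
    stop("ranking lists unknown term(s): ", paste(extra, collapse = ", "))
  lv <- severity_level(terms, vocabulary)
  if (is.unsorted(lv))
    stop("ranking violates category ordering (LoF > missense > synonymous > ",
         "non-exonic): ", paste(terms[which(diff(lv) < 0L)], collapse = ", "))
  structure(list(vocabulary = vocabulary, terms = terms),
            class = "vc_severity_ranking")
}

#' Load a severity ranking from a YAML config
#'
#' The file holds `vocabulary:` and `terms:` (a list, most severe first);
#' the shipped defaults live at
#' `system.file("extdata", "a_style_severity.yaml", package = "varconcord")`
#' and the v_style equivalent.
#'
#' @param path YAML file.
#' @param vocabulary expected vocabulary (checked against the file).
#' @return `vc_severity_ranking`.
#' @export
load_ranking <- function(path, vocabulary = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$vocabulary) || is.null(cfg$terms))
    stop("ranking config needs 'vocabulary' and 'terms': ", path)
  if (!is.null(vocabulary) && cfg$vocabulary != vocabulary)
    stop("ranking config is for ", cfg$vocabulary, ", expected ", vocabulary)
  severity_ranking(cfg$vocabulary, unlist(cfg$terms))
}

severity_rank <- function(terms, ranking) {
  r <- match(terms, ranking$terms)
  if (anyNA(r))
    stop("term(s) absent from ranking: ",
         paste(unique(terms[is.na(r)]), collapse = ", "))
  r
}

#' Select the most severe consequence call
#'
#' Returns the call whose term ranks first; ties are broken by lexicographic
#' transcript id (calls without a transcript sort last) so selection is
#' deterministic and order-independent.
#'
#' @param calls non-empty data.frame of consequence calls with columns
#'   `term` and `transcript_id`.
#' @param ranking `vc_severity_ranking` covering every term present.
#' @return the selected call (one-row data.frame).
#' @export
most_severe <- function(calls, ranking) {
  if (!nrow(calls)) stop("most_severe() on an empty call set")
  r <- severity_rank(calls$term, ranking)
  ord <- order(r, is.na(calls$transcript_id), calls$transcript_id)
  calls[ord[1L], , drop = FALSE]
}
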