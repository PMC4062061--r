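# Harmonization of the two consequence vocabularies.
#
# category: term -> high-level category used for CATEGORY matching.
#   Donor/acceptor splice terms and the broad A_style splicing term are LoF;
#   general splice-region variants sit at missense level; stop-retained and
#   other-coding are synonymous-level. Terms not fixed by those constraints
#   are mapped by this shipped default (an assumption, overridable here).
# equivalence: A_style term -> exactly-equivalent V_style term(s).
#   The broad splicing term is equivalent to all three fine splice terms;
#   initiator codon, stop retained and other coding have no A_style
#   equivalent; "unknown" matches nothing, not even itself.
category:
  A_style:
    stopgain_SNV: LOF
    stoploss_SNV: LOF
    splicing: LOF
    frameshift_insertion: LOF
    frameshift_deletion: LOF
    frameshift_substitution: LOF
    nonsynonymous_SNV: MISSENSE
    nonframeshift_insertion: MISSENSE
    nonframeshift_deletion: MISSENSE
    nonframeshift_substitution: MISSENSE
    synonymous_SNV: SYNONYMOUS_OTHER
    UTR5: UTR
    UTR3: UTR
    ncRNA_splicing: NCRNA
    ncRNA_exonic: NCRNA
    ncRNA_intronic: NCRNA
    intronic: INTRONIC
    upstream: INTERGENIC_FLANK
    downstream: INTERGENIC_FLANK
    intergenic: INTERGENIC_FLANK
    unknown: UNKNOWN
  V_style:
    stop_gained: LOF
    stop_lost: LOF
    frameshift_variant: LOF
    splice_donor_variant: LOF
    splice_acceptor_variant: LOF
    missense_variant: MISSENSE
    initiator_codon_variant: MISSENSE
    inframe_insertion: MISSENSE
    inframe_deletion: MISSENSE
    splice_region_variant: MISSENSE
    synonymous_variant: SYNONYMOUS_OTHER
    stop_retained_variant: SYNONYMOUS_OTHER
    coding_sequence_variant: SYNONYMOUS_OTHER
    5_prime_UTR_variant: UTR
    3_prime_UTR_variant: UTR
    non_coding_transcript_splice_variant: NCRNA
    non_coding_exon_variant: NCRNA
    non_coding_intron_variant: NCRNA
    intron_variant: INTRONIC
    upstream_gene_variant: INTERGENIC_FLANK
    downstream_gene_variant: INTERGENIC_FLANK
    intergenic_variant: INTERGENIC_FLANK
    unknown: UNKNOWN
equivalence:
  stopgain_SNV: [stop_gained]
  stoploss_SNV: [stop_lost]
  frameshift_insertion: [frameshift_variant]
  frameshift_deletion: [frameshift_variant]
  frameshift_substitution: [frameshift_variant]
  splicing: [splice_donor_variant, splice_acceptor_variant, splice_region_variant]
  nonsynonymous_SNV: [missense_variant]
  nonframeshift_insertion: [inframe_insertion]
  nonframeshift_deletion: [inframe_deletion]
  nonframeshift_substitution: [inframe_insertion, inframe_deletion]
  synonymous_SNV: [synonymous_variant]
  UTR5: [5_prime_UTR_variant]
  UTR3: [3_prime_UTR_variant]
  ncRNA_splicing: [non_coding_transcript_splice_variant]
  ncRNA_exonic: [non_coding_exon_variant]
  ncRNA_intronic: [non_coding_intron_variant]
  intronic: [intron_variant]
  upstream: [upstream_gene_variant]
  downstream: [downstream_gene_variant]
  intergenic: [intergenic_variant]
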