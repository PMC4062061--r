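# Default severity ranking for the V_style vocabulary, most severe first.
# Donor/acceptor splice terms sit in the LoF block; splice_region ranks at
# missense level (above synonymous, below missense-class coding changes).
vocabulary: V_style
terms:
  - stop_gained
  - stop_lost
  - frameshift_variant
  - splice_donor_variant
  - splice_acceptor_variant
  - missense_variant
  - initiator_codon_variant
  - inframe_insertion
  - inframe_deletion
  - splice_region_variant
  - synonymous_variant
  - stop_retained_variant
  - coding_sequence_variant
  - 5_prime_UTR_variant
  - 3_prime_UTR_variant
  - non_coding_transcript_splice_variant
  - non_coding_exon_variant
  - non_coding_intron_variant
  - intron_variant
  - upstream_gene_variant
  - downstream_gene_variant
  - intergenic_variant
  - unknown
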