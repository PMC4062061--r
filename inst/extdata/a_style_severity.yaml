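# Default severity ranking for the A_style vocabulary, most severe first.
# Constraints honoured: stop-gain ranks above frameshift (the stop-scan
# reporting convention), the broad splicing term sits in the LoF block, and
# the category blocks are ordered LoF > missense-level > synonymous-level >
# non-exonic. Within-block order beyond those constraints is one possible
# common-sense choice; any permutation respecting the blocks validates.
vocabulary: A_style
terms:
  - stopgain_SNV
  - stoploss_SNV
  - splicing
  - frameshift_insertion
  - frameshift_deletion
  - frameshift_substitution
  - nonsynonymous_SNV
  - nonframeshift_insertion
  - nonframeshift_deletion
  - nonframeshift_substitution
  - synonymous_SNV
  - UTR5
  - UTR3
  - ncRNA_splicing
  - ncRNA_exonic
  - ncRNA_intronic
  - intronic
  - upstream
  - downstream
  - intergenic
  - unknown
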