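# Mapping from ANNOVAR refGene consequence strings to the internal
# consequence classes. Strings not listed here classify as "other".
# Matching is case-insensitive after trimming whitespace.
vocabulary:
  "nonsynonymous SNV": missense
  "missense": missense
  "missense_variant": missense
  "synonymous SNV": synonymous
  "synonymous": synonymous
  "synonymous_variant": synonymous
  "stopgain": stopgain
  "stopgain SNV": stopgain
  "stop_gained": stopgain
  "stoploss": stoploss
  "stoploss SNV": stoploss
  "stop_lost": stoploss
  "frameshift insertion": frameshift_indel
  "frameshift deletion": frameshift_indel
  "frameshift substitution": frameshift_indel
  "frameshift_variant": frameshift_indel
  "nonframeshift insertion": inframe_indel
  "nonframeshift deletion": inframe_indel
  "nonframeshift substitution": inframe_indel
  "inframe_insertion": inframe_indel
  "inframe_deletion": inframe_indel
  "splicing": splicing
  "splice_acceptor_variant": splicing
  "splice_donor_variant": splicing
  "UTR5": utr5
  "5_prime_UTR_variant": utr5
  "UTR3": utr3
  "3_prime_UTR_variant": utr3
  "intronic": intronic
  "intron_variant": intronic
  "intergenic": intergenic
  "intergenic_variant": intergenic
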