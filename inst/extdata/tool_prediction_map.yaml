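# Deleterious-call conventions for the dbNSFP prediction tools.
# categorical tools: any value in `deleterious` counts as a deleterious
# call; any other non-missing value counts as benign. numeric tools are
# called deleterious at or above `cutoff`. "." is always missing.
tools:
  sift:
    kind: categorical
    deleterious: [D]
  polyphen2_hdiv:
    kind: categorical
    deleterious: [D, P]
  polyphen2_hvar:
    kind: categorical
    deleterious: [D, P]
  lrt:
    kind: categorical
    deleterious: [D]
  mutationtaster:
    kind: categorical
    deleterious: [A, D]
  mutationassessor:
    kind: categorical
    deleterious: [H, M]
  fathmm:
    kind: categorical
    deleterious: [D]
  provean:
    kind: categorical
    deleterious: [D]
  metasvm:
    kind: categorical
    deleterious: [D]
  metalr:
    kind: categorical
    deleterious: [D]
  mcap:
    kind: categorical
    deleterious: [D]
  cadd_phred:
    kind: numeric
    cutoff: 20
# splice-capable tools used for the splicing-variant sub-score; hsf is an
# imported Human Splicing Finder verdict column (never queried).
splice_tools:
  mutationtaster:
    kind: categorical
    deleterious: [A, D]
  cadd_phred:
    kind: numeric
    cutoff: 20
  bayesdel:
    kind: numeric
    cutoff: -0.057
  hsf:
    kind: categorical
    deleterious: [affected]
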