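- name: GNAQ_Q209
  anchor_seq: ACTGGTCA
  stem_seq: GCGCATGCGC
  reference_seq: TTCAGGTCCTTAGAAACGGGTATCTCGATGTAGCCA
  barcode_length: 12
  target_position: 14
  target_ref: A
  target_alts:
  - T
  - C
- name: GNA11_Q209
  anchor_seq: TGACCAGT
  stem_seq: GCGCATGCGC
  reference_seq: CCATTGACGTTAACAGGGTCATAGGCTTTCAGACTG
  barcode_length: 12
  target_position: 14
  target_ref: A
  target_alts:
  - T
- name: CYSLTR2_L129
  anchor_seq: GATCGTTG
  stem_seq: GCGCATGCGC
  reference_seq: AGGTCTTGAACCTGACATGATTCGCCTAGAGTTACC
  barcode_length: 12
  target_position: 12
  target_ref: T
  target_alts:
  - A
- name: PLCB4_D630
  anchor_seq: CTAGGACT
  stem_seq: GCGCATGCGC
  reference_seq: GTTACCAGATTCGAAGACTGGTCTTAGCACGTATTG
  barcode_length: 12
  target_position: 15
  target_ref: G
  target_alts:
  - T
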