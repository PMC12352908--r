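name: example-exon-guide
reference: CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGCGCGGATAAATGTGTTCGATGTAACCTGCTCAGCAATGCTGGAGCGGCACGGACCACATGCATTGTTAGAGCAACAGGCCAAGTTCACGCGGTAGCGATAGACGCGTCGCGTATCACGGAGTACTCGCAAATGAAGGGCATTCCCTGTATCTTCGGCAAATATATATAAGGTCGGAGGTAGAATCCT
regions:
- start: 0
  end: 140
  kind: exon
- start: 140
  end: 220
  kind: intron
cut_site: 100
mut_substitutions:
- position: 98
  ref: T
  alt: C
wtstar_substitutions:
- position: 95
  ref: T
  alt: C
coding_frame_offset: 0
splice_window: 2
arm_reach: 60
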