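# Example DmCC haplotype registry -- ENTIRELY SYNTHETIC.
# Entry names mirror the classical reference panel (C1, C2, C3, A2, Z1)
# but primers H2/E2, reference windows, fragment sizes and lineage bins are
# generated fixtures. For real genotyping, replace H2/E2 with the originally
# published DmCC primer sequences, and populate expected_sizes /
# reference_sequence from the published haplotype literature or by digesting
# reference accessions (e.g. KX908209, HM117905) with this tool.

primers:
  H2: AACGGACGATGCGTGTATGG
  E2: CGAAACATCTTTCGTGCCAC
  COI_Seq-F: ACCACCTCTAGATCATTCACATTT
  COII_Seq-R: AGGATGGAACTGTTCATGAATGAA
enzyme:
  name: DraI
  recognition: TTTAAA
  cut_offset: 3
  palindromic: yes
lineage_bins:
  C:
  - 500
  - 760
  A:
  - 770
  - 1020
tolerance:
  absolute_bp: 3
  relative: 0.02
min_visible: 15
haplotypes:
- name: C1
  lineage: C
  subspecies_label: synthetic ligustica-like
  expected_sizes:
  - 245
  - 214
  - 131
  reference_sequence: AACGGACGATGCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCTTTAAAATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGATTTAAAAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGGGGTAAGGCTTTAGGCCATTGAGAAATAAGCGTGGGTACATCCCTTGCTTGAGCTAGATTGTACTCAGAACGGGCGGTGAGATAACTATGGAACTAAAGGAAATATTTCTGAATGGGTGGCCAATCGGTGGACTAGTCGACTGCGTTCTCTTATAGTCGTTCGTTGTCATGTGGCACGAAAGATGTTTCG
- name: C2
  lineage: C
  subspecies_label: synthetic carnica-like
  expected_sizes:
  - 247
  - 218
  - 110
  - 45
  reference_sequence: AACGGACGATGCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCAGGATTTAAATCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACTTTAAATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATTTTAAACTACTACTAAGAAGTGCGCCCCCGAGCGGCAGAATCGCGTTTAATACAGCTGAACGCCGTCGAAATCTCAAACTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAACTAGCGGGATTAACGTTCGTATTAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAAAGTACAGGTTATTTGCCTCCTCCTAGTGGGTACTGGTCCATGTTCTTTCCGTGGCACGAAAGATGTTTCG
- name: C3
  lineage: C
  subspecies_label: ''
  expected_sizes:
  - 487
  - 163
  reference_sequence: AACGGACGATGCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGTTTAAAGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAGTGCCCCATAAGCATAGCAATTGAACAGCACATGCCGTCGCAAATCGGAACGAGATCTAGGGGATAATCATGACCACGACCATCACCTTTTACTTCACAACTCGACAAGCATTCGGTTGACGTGTCGTACCCTGGCGCCACGCGTCCGAAGATATCGTTCTCGCCTTGGTGAAGAGCGAAATTTTCAGGTGTCCCCGGCTCTCAGTCGATTCAGCTAACCGTGTGTTAGGTGGCACGAAAGATGTTTCG
- name: A2
  lineage: A
  subspecies_label: ''
  expected_sizes:
  - 535
  - 215
  - 80
  reference_sequence: AACGGACGATGCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCATTTAAATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTCACGATCTTTATCTTTAAAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGCCGCAACGTAAGCGTGGTTCAGGGTGGCCTTATGTGTTCTCTGCATTAAAATGGGGAGTAACCGAGAAGACGTCTGGGTTGGCGGCCATGAGGCCTGTTCGCCTTTTGCATAGCTTCATGAATCCAGGAGGTGCGTTATCAGCCTATCCTTAGCGGACATAGGTGCGAGTCTCAAATGGTTAGGCGAGTGATCTCCAATTACAAGCTAAGGAGAACGTATGTTATCCGAGCCCCAAGGCAGACAAGCAGTATAGGTGGTCATGCTGCACATGCTATTGAAGATTTGTGGTTACTCGAAGGACGCAGCTCACTCCCAGGCGTGGCCTTTACGCCTTCAATTCCAAACCCAGCCACCTCCCTCTCCACAAACATGGATATGAGTCGGGGGACGCTGAGAACGTGGTGAGTTTGTGGCACGAAAGATGTTTCG
- name: Z1
  lineage: A
  subspecies_label: ''
  expected_sizes:
  - 515
  - 236
  - 77
  - 32
  reference_sequence: AACGGACGATGCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCAGGAGGATCGTCGGTCTTACCTTTTAAAGTAGTAATGATAGGATCTCACACTACTTTAAAGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGATTTAAAAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAGTCCTTAGTGCCTCCATATTAGAGTCGTAGCGACCGGCCGCCAACACCATGCTCTTGTATTCAAATTCGACAATCCTCTACCGAAGGGAAAAACTTCGCATTTATACCAAACCCTATTTATCTATAATTCTCCCAGCACGCCCACCGAATTCAATTACGTCATGTCCGTAAATTCACGGACGTCTCACGCATGATTTATGGAAAAGGGCGTAATTCTTGAAAGGCCTGCTTAGCGCTAGCGCTCCTTAATCGGTTCGGCCAGCCTGCATTCGACCAGCATTAACCACTGAGGTAGAACCGGACCTGCTGACTATTGCATGATGTCCGGATTTTCCCTCTGCTCCATTAACAATATTGCAATTTTGTGACGCGGGCCGCGAGCTGAACAGTTAGGTAGGACACATACTCACTAAAGACGGACGGCGTGGCCCCACCTCATGTGGCACGAAAGATGTTTCG
elements:
  COI_3prime: ATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCT
  tRNA_Leu: TGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGAT
  Q_fragment: AAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTTCTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCG
  COII_5prime: AATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCCTTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGCCGTGAAAGGATCTCTGACTATCACAACCGTGAATGTCAGATGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTATCAGGGGAGTTGGATCGGGCTGGAGGAAATAGTATCAGGCCGGGGACTGAGTGCGTACCCTCCTGCGCCTGCTGCGACCGTGACAGCGAGCAGCGTTTTAGGATGCGAGGGGGACCTTATTGAAGTACGGAGAGTCTGCAAACTTGCACTCAACCCCCCTGATCAGAAGAGCGCGACTCCACACTTACACCTAGCGCCATACACGCGGTACGCCCCGAAGCGTCGAAGTTGGGTCCCTGTAA
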