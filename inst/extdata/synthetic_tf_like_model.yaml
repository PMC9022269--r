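subfamily: SimTf
pattern_id: default
notes: 'synthetic example model: random ancestral monomer with diverged copies; not
  a real subfamily consensus'
monomers:
- CCTATAATCTACCCCCAGAGGACAGTGGCCGGGCTACACTCGCATAGTTATTTAAATCATCGGTCTCATGAAAGTCCATCCCACAGTGCGTCGGGTGGGAGTTGTCCTAAATCTGGTTAGCATAGCAGACTCAGCTCTGTGAAGTGATTTAGTCCAGATATTCTCCGAGATCTGAGCATCAACGCGTGACAAACGTGACACGTCAACGATTA
- CCTATAATCTACCCGCTGAGGACACTGGTCGGGCTACGCTCTCATTGCTAGGTAAAACATCGATCTCGCGAATGTCCATCCCCCAGTGTGTCAGGTGGGTGATGTACTAAATCTAGCTAGAATAGCAGACTCTGCTCTCTGAAGTGATTTAGTCCAGATAATCACGGAGATCTCAGCATCCACGCGTGACAAACGTGACCCGTCAACGATTA
- CATATGTCCTACGCGCAGATGACAGTGGCCGGGCTACGCTCGTATTGTTAAGTAAGTCATCGATCACACGGATCTCCATCCGACAGTGTGTCGGGTGGGTGTTGTACTAACTCTCGCTCGACTATCAGACGCATCTCTTTGATATGATTTAGTCCAGATATTCTCGGCGATCTGAGCATCAACGCGTGACAAATGTG
tether: GTGAACACGTTTGTTCTATCGCTCCTGCTTCGAATCAATTCCAGGGACACCCGTGGGTTGGAACATGCAATCGACCCAGCAGGACGAACATAGATCAGCTAGTGTCAACTTATGTTTGCCGAATACAGGCGGCTTGGAGAAAGTGGTTCATTATGGTGATACGGTTAAATTTGGCATAGGTATATATGACCAGAGTAGGCCAAGA
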