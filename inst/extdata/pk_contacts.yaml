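# Native pseudoknot (kissing-loop) contacts of the 2'-dG aptamer.
# Base-pair distance convention: purine N1 against pyrimidine N3.
# Stack distance: unweighted centroid of the listed base atoms.
- label: G45-C69
  kind: basepair
  residue_a: 45
  residue_b: 69
  atom_a: N1
  atom_b: N3
  threshold: 4.0
- label: G46-C68
  kind: basepair
  residue_a: 46
  residue_b: 68
  atom_a: N1
  atom_b: N3
  threshold: 4.0
- label: A42-A71
  kind: stack
  residue_a: 42
  residue_b: 71
  atom_a: [N1, C2, N3, C4, C5, C6, N7, C8, N9]
  atom_b: [N1, C2, N3, C4, C5, C6, N7, C8, N9]
  threshold: 5.0
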