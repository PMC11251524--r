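# Default secondary-structure partition of the 2'-dG (mfl) aptamer,
# crystal-structure residue numbering.  Anchors: G34/G35 on P2; A42, G45,
# G46 on L2; C68, C69, A71 on L3; U74 on P3; C80 on J31.  J31 is two
# residues wide and J12 three (P1 is separated from P3 by two residues and
# from P2 by three).  Range boundaries between anchors are interpolated
# from the secondary-structure cartoon; override with a custom map when an
# exact partition is available.
offset: -4          # crystal -> experimental numbering (C80 -> C76)
P1A: [19-25]
J12: [26-28]
P2:  [29-36, 48-55]
L2:  [37-47]
J23: [56-59]
P3:  [60-65, 73-78]
L3:  [66-72]
J31: [79-80]
P1B: [81-87]
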