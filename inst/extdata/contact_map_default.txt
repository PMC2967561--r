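# Default contact map: 38 contacting (domain position, peptide position)
# pairs covering all 16 aligned binding-site positions and all 5 C-terminal
# peptide positions (p-4..p0). The pair count and coverage reproduce the
# structural constants of the mouse alpha1-syntrophin PDZ-peptide complex
# (residue pairs within 5 A); the identity of the individual pairs is a
# SYNTHETIC RECONSTRUCTION, since the original pair list is not published.
# Format: domain_pos peptide_pos
1 p0
1 p-1
2 p0
2 p-1
2 p-2
3 p0
3 p-1
4 p0
4 p-2
5 p0
5 p-1
6 p0
6 p-2
6 p-3
7 p-1
7 p-3
8 p0
8 p-1
8 p-2
9 p-2
9 p-3
10 p-2
10 p-3
10 p-4
11 p-3
11 p-4
12 p-2
12 p-4
13 p-1
13 p-2
13 p-3
14 p0
14 p-2
15 p-2
15 p-3
15 p-4
16 p-3
16 p-4
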