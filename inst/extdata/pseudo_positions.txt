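# Class-I heavy-chain contact positions defining the 34-residue
# pseudo-sequence (1-based on the mature chain), as defined for the
# NetMHCpan pseudo-sequence (Nielsen et al. 2007, PLoS ONE 2:e796):
# residues within contact distance of the bound peptide, polymorphic
# across alleles.
7
9
24
45
59
62
63
66
67
69
70
73
74
76
77
80
81
84
95
97
99
114
116
118
143
147
150
152
156
158
159
163
167
171
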