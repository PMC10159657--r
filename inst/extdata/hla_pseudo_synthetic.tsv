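# SYNTHETIC demonstration panel - NOT real HLA pseudo-sequences.
# Allele names use the fictitious 90:xx range so they cannot be mistaken
# for real typing results. For real analyses supply a pseudo-sequence map
# derived from IMGT/HLA heavy-chain sequences via read_hla_fasta() or
# read_pseudo_map().
HLA-A*90:01	NHWWCQLRVDKPWAATSTQETSVSRRAFKIRESQ
HLA-A*90:02	PKCRKSFKRNGIEKHPLWWCTNKTVNTWRTGQGG
HLA-A*90:03	LFMLDGVPGTYDKYQADRVYPNYAAIKKINRIKV
HLA-A*90:04	YIEAEHFKKPPCQWMELDMADDINEHMGLFNLQQ
HLA-A*90:05	YMIQKVYSGIRAHAQPRFTHFCIWFVVVSGPEGL
HLA-A*90:06	RNPIGFNLDINLWCLPKHNWRAVDKPMDEREYRW
HLA-A*90:07	NLENIACAEETPLVRCKGDTSALCWAIQTRWMWF
HLA-A*90:08	PAVRGYPLTTVVGVNGNHTAHNWMNFTWCVRYNT
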