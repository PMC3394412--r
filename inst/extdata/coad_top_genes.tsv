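# Selected highly mutated genes from a published 100-patient colon
# adenocarcinoma cohort: occurrence-weighted mutation count and
# representative (longest-isoform) protein length.
gene	protein_acc	mutations	protein_length
APC	NP_001120982	76	2843
BRAF	NP_004324	14	766
FBXW7	NP_361014	21	745
KRAS	NP_203524	30	189
LOC440563	NP_001130033	33	293
NRAS	NP_002515	7	189
OR8U1	NP_001005204	48	309
TAS2R19	NP_795369	22	299
TAS2R30	NP_001091112	28	319
TAS2R31	NP_795366	31	309
TAS2R43	NP_795365	36	309
TP53	NP_000537	31	393
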