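# Selected highly mutated domains in a published 100-patient colon
# adenocarcinoma cohort: occurrence-weighted mutation count and cumulative
# domain length (summed residue length of all placements across the
# representative protein set).
domain_name	domain_acc	mutations	cumulative_length
APC_basic	PF05956	5	356
APC_crr	PF05923	8	176
CortBP2	PF09727	9	726
MH2	PF03166	14	731
Miro	PF08477	77	5861
MutS_IV	PF05190	6	380
PI3K_p85B	PF02192	4	231
P53	PF00870	28	390
TAS2R	PF05296	132	6557
WAP	PF00095	6	299
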