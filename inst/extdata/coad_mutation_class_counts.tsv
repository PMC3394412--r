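# Mutation-class counts for a published 100-patient colon adenocarcinoma
# exome cohort (retained somatic mutations after filtering).  `in_domain` is
# the number of mutations falling inside annotated domain regions;
# `n_patients` the cohort size.
item	n
nsSNV	17174
frameshift_ins	2527
nonframeshift_ins	239
frameshift_del	5
nonframeshift_del	0
stoploss_SNV	33
stopgain_SNV	1594
in_domain	10647
n_patients	100
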