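gene	tissue	efficiency
Ef1a	head_kidney	2.05
Ef1a	spleen	2.09
sIgM	head_kidney	2.05
sIgM	spleen	2.02
mIgM	head_kidney	2.06
mIgM	spleen	2.05
IgT	head_kidney	2.04
IgT	spleen	2.02
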