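comparison	hypermethylated	hypomethylated	total
OA_vs_Control	215	191	406
EAT_vs_OA	296	236	532
ECB_vs_OA	109	156	265
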