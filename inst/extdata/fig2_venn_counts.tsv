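category	count
oa_hyper_eat_hypo	22
oa_hypo_eat_hyper	39
oa_hyper_ecb_hypo	11
oa_hypo_ecb_hyper	9
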