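test	statistic	p_value	n	n_zero	method	alternative
wilcoxon_signed_rank	15	0.03125	5	0	exact sign enumeration	greater
sign_flip_permutation	3.0405925939971508	0.03125	5	NA	full enumeration	greater
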