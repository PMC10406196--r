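subject	relative_index	n_obs
1	2.889719033457038	8
2	3.2421008552894595	8
3	3.3216324637599213	8
4	2.427627751310363	8
5	3.3218828661689712	8
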