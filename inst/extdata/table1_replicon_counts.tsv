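replicon	n_genes	n_up	n_down
pMHa	257	59	18
pMHb	447	105	26
chromosome	6562	702	955
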