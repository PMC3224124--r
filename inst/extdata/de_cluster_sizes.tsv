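cluster	n_genes
stressed_leaf	355
leaf	127
stressed_berry	127
berry	130
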