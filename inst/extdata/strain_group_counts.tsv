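scope	lifestyle	n_strains
full	aerobic	344
full	anaerobic	1284
restricted-branch	aerobic	87
restricted-branch	anaerobic	138
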