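truth	i	M	o
i	7323	442	1118
M	1819	9884	1417
o	1117	775	6007
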