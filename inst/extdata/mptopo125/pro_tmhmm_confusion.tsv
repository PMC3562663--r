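truth	i	M	o
i	7574	450	859
M	1922	9588	1610
o	1051	714	6134
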