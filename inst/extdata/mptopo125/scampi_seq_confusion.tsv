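truth	i	M	o
i	7359	455	1069
M	1907	9628	1585
o	1101	564	6234
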