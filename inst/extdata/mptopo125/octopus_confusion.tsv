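truth	i	M	o
i	7655	389	839
M	1877	9785	1458
o	1230	578	6091
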