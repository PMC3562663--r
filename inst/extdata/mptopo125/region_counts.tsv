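predictor	n_obs	n_prd	n_cor
OCTOPUS	515	512	500
PRO	515	512	498
PRODIV	515	524	503
SCAMPI-msa	515	512	500
SCAMPI-seq	515	507	494
TOPPER	515	507	500
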