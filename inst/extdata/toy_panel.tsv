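gene	rvis_percentile	background_carrier_prob	chromosome
GENEA	2	0.08	1
GENEB	50	0.05	2
GENEC	90	0.10	X
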