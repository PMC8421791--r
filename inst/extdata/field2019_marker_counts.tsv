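marker	group	n_gigi_hom	n_het	n_maize_hom	chi2_printed	p_printed
chr2_44.6Mb	RG	14	18	3	6.837	0.0328
chr2_44.6Mb	NRG	15	43	13	3.717	0.1559
chr7_4.5Mb	RG	6	19	10	1.346	0.5101
chr7_4.5Mb	NRG	22	35	14	1.778	0.4111
chr8_139.5Mb	RG	7	15	13	2.458	0.2927
chr8_139.5Mb	NRG	20	29	22	2.140	0.3431
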