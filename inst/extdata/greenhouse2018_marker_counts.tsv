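marker	n_gigi_hom	n_het	n_maize_hom	chi2_printed	p_printed
chr2_44.6Mb	30	55	7	15.022	0.0005
chr7_4.5Mb	18	44	32	4.254	0.1192
chr8_139.5Mb	43	41	12	22.063	1e-04
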