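exposure	outcome	n_snp	or	ci_low	ci_high	p_ivw	p_heterogeneity	p_pleiotropy	reverse_p
C-C motif chemokine 25 levels	KOA	35	0.904	0.843	0.969	0.004	0.387	0.288	0.557
T-cell surface glycoprotein CD5 levels	KOA	31	0.867	0.760	0.990	0.035	0.226	0.761	0.858
C-X-C motif chemokine 9 levels	KOA	40	1.150	1.001	1.320	0.048	0.128	0.506	0.346
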