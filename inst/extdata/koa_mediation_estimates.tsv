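exposure	mediator	outcome	beta1	beta2	total_beta	reported_proportion
T-cell surface glycoprotein CD5 levels	rQTL-ANGPTL3/TFPI	KOA	-0.084	0.159	-0.143	9.340
T-cell surface glycoprotein CD5 levels	rQTL-CPA1/CTRB1	KOA	-0.178	-0.095	-0.143	-11.825
T-cell surface glycoprotein CD5 levels	rQTL-HAGH/HBQ1	KOA	0.097	0.132	-0.143	-8.954
C-X-C motif chemokine 9 levels	rQTL-COMP/DPP4	KOA	-0.208	0.134	0.140	-19.909
C-X-C motif chemokine 9 levels	rQTL-MSRA/P4HB	KOA	-0.177	-0.230	0.140	29.079
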