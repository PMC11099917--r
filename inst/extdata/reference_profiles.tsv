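fibril	aar_direct_bind	tht_s5h_bind	tht_bta_bind	tht_oxi_bind	tht_thr_bind	aar_tht_bind	oxi_bs1_class	s5h_kd_class	aar_kd_class
F	TRUE	FALSE	FALSE	TRUE	NA	NA	high	NA	NA
R	FALSE	FALSE	FALSE	TRUE	NA	NA	low	NA	NA
f65	TRUE	FALSE	TRUE	TRUE	NA	NA	high	NA	NA
f91	FALSE	TRUE	TRUE	TRUE	NA	NA	high	NA	NA
f110	TRUE	FALSE	TRUE	TRUE	NA	NA	low	NA	NA
PD	TRUE	TRUE	TRUE	TRUE	NA	NA	high	lowest	other
MSA	TRUE	TRUE	TRUE	TRUE	NA	NA	high	other	lowest
DLB	TRUE	TRUE	TRUE	TRUE	NA	NA	high	other	other
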