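fibril	field	value	basis
F	aar_direct_bind	TRUE	observed
R	aar_direct_bind	FALSE	observed
f65	aar_direct_bind	TRUE	observed
f91	aar_direct_bind	FALSE	observed
f110	aar_direct_bind	TRUE	observed
PD	aar_direct_bind	TRUE	observed
MSA	aar_direct_bind	TRUE	observed
DLB	aar_direct_bind	TRUE	observed
F	tht_s5h_bind	FALSE	observed
R	tht_s5h_bind	FALSE	observed
f65	tht_s5h_bind	FALSE	observed
f91	tht_s5h_bind	TRUE	observed
f110	tht_s5h_bind	FALSE	observed
PD	tht_s5h_bind	TRUE	observed
MSA	tht_s5h_bind	TRUE	observed
DLB	tht_s5h_bind	TRUE	observed
F	tht_bta_bind	FALSE	observed
R	tht_bta_bind	FALSE	observed
f65	tht_bta_bind	TRUE	observed
f91	tht_bta_bind	TRUE	implied
f110	tht_bta_bind	TRUE	observed
PD	tht_bta_bind	TRUE	implied
MSA	tht_bta_bind	TRUE	implied
DLB	tht_bta_bind	TRUE	implied
F	tht_oxi_bind	TRUE	observed
R	tht_oxi_bind	TRUE	observed
f65	tht_oxi_bind	TRUE	implied
f91	tht_oxi_bind	TRUE	observed
f110	tht_oxi_bind	TRUE	implied
PD	tht_oxi_bind	TRUE	implied
MSA	tht_oxi_bind	TRUE	implied
DLB	tht_oxi_bind	TRUE	implied
F	tht_thr_bind	NA	not_reported
R	tht_thr_bind	NA	not_reported
f65	tht_thr_bind	NA	not_reported
f91	tht_thr_bind	NA	not_reported
f110	tht_thr_bind	NA	not_reported
PD	tht_thr_bind	NA	not_reported
MSA	tht_thr_bind	NA	not_reported
DLB	tht_thr_bind	NA	not_reported
F	aar_tht_bind	NA	not_reported
R	aar_tht_bind	NA	not_reported
f65	aar_tht_bind	NA	not_reported
f91	aar_tht_bind	NA	not_reported
f110	aar_tht_bind	NA	not_reported
PD	aar_tht_bind	NA	not_reported
MSA	aar_tht_bind	NA	not_reported
DLB	aar_tht_bind	NA	not_reported
F	oxi_bs1_class	high	observed
R	oxi_bs1_class	low	observed
f65	oxi_bs1_class	high	observed
f91	oxi_bs1_class	high	observed
f110	oxi_bs1_class	low	observed
PD	oxi_bs1_class	high	observed
MSA	oxi_bs1_class	high	observed
DLB	oxi_bs1_class	high	observed
PD	s5h_kd_class	lowest	significant_difference
MSA	s5h_kd_class	other	significant_difference
DLB	s5h_kd_class	other	significant_difference
f91	s5h_kd_class	NA	not_reported
MSA	aar_kd_class	lowest	significant_difference
DLB	aar_kd_class	other	significant_difference
PD	aar_kd_class	other	significant_difference
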