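assay_id	fibril_a	fibril_b	basis
aar_direct	MSA	DLB	significant_kd_difference
aar_direct	MSA	PD	significant_kd_difference
tht_s5h	PD	MSA	significant_kd_difference
tht_s5h	PD	DLB	significant_kd_difference
tht_oxi	R	F	significant_bs1_difference
tht_oxi	R	f65	significant_bs1_difference
tht_oxi	R	f91	significant_bs1_difference
tht_oxi	R	PD	significant_bs1_difference
tht_oxi	R	MSA	significant_bs1_difference
tht_oxi	R	DLB	significant_bs1_difference
tht_oxi	f110	F	significant_bs1_difference
tht_oxi	f110	f65	significant_bs1_difference
tht_oxi	f110	f91	significant_bs1_difference
tht_oxi	f110	PD	significant_bs1_difference
tht_oxi	f110	MSA	significant_bs1_difference
tht_oxi	f110	DLB	significant_bs1_difference
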