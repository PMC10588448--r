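gene	subset	tier_group	cancer_af	control_af	case_alt	case_total	control_alt	control_total	p_greater_pub	or_pub	fdr_greater_pub	p_two_sided_pub	fdr_two_sided_pub	shifted
RPA1	PanCancer	ULTRA_RARE_PLUS_NOVEL	0.0029	0.0017	35	11951	466	267908	0.00350858	1.6837	0.028068639	0.00531368	0.042509437	FALSE
RPA1	HEM	ULTRA_RARE_PLUS_NOVEL	0.0022	0.0017	15	6889	466	267908	0.231331347	1.2518	0.462662694	0.37871645	0.504955267	FALSE
RPA1	ST	ULTRA_RARE_PLUS_NOVEL	0.0033	0.0017	13	3935	466	267908	0.024524772	1.8993	0.09809909	0.031863803	0.127455213	FALSE
RPA1	CNS	ULTRA_RARE_PLUS_NOVEL	0.0033	0.0017	7	2129	466	267908	0.083930393	1.8903	0.223814382	0.107377392	0.214754784	FALSE
RPA2	PanCancer	ULTRA_RARE_PLUS_NOVEL	0.0006	0.0007	7	11979	200	268174	0.785228312	NA	NA	NA	NA	TRUE
RPA3	PanCancer	ULTRA_RARE_PLUS_NOVEL	0.0008	0.0006	9	11977	164	268210	0.32195265	NA	NA	NA	NA	TRUE
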