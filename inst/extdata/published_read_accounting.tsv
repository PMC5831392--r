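category	DU_total	DU_percent	CE_total	CE_percent	CO_total	CO_percent
raw_reads	28536048	NA	27878234	NA	26097405	NA
high_quality_reads	28493897	100	27836933	100	26057470	100
no_3_adapter	268000	0.94	443102	1.59	248668	0.95
insert_null	19580	0.07	443102	1.59	15055	0.06
adapter5_contaminant	9650	0.03	9981	0.04	8662	0.03
short_lt18	697631	2.45	874414	3.14	433880	1.67
polyA	145	0	135	0	88	0
clean_reads	27498891	96.51	26490229	95.16	25351117	97.29
mapped_reads	16733785	60.85	17005544	64.2	16567397	65.35
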