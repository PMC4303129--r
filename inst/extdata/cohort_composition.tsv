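characteristic	level	count	printed_pct
age_band	<50	318	62
age_band	50+	199	38
race	white_other	301	58
race	african_american	216	42
menopausal_status	pre	275	53
menopausal_status	post	242	47
subtype	luminal_A	212	51
subtype	luminal_B	65	16
subtype	basal_like	86	21
subtype	her2_hr_neg	26	6
subtype	unclassified	24	6
p53_status	mutant	218	42
p53_status	wild_type	297	58
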