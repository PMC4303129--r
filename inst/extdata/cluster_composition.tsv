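characteristic	cluster	level	count	printed_pct
hr_status	2	positive	20	20
hr_status	2	negative	81	80
subtype	2	luminal_A	12	14
subtype	2	luminal_B	5	6
subtype	2	basal_like	54	61
subtype	2	her2_hr_neg	7	8
subtype	2	unclassified	10	11
subtype	3	luminal_A	52	64
subtype	3	luminal_B	17	21
subtype	3	basal_like	3	4
subtype	3	her2_hr_neg	8	10
subtype	3	unclassified	1	1
p53_status	3	mutant	25	25
p53_status	3	wild_type	74	75
p53_status	2	mutant	90	83
p53_status	2	wild_type	18	17
grade	2	1	3	3
grade	2	2	16	15
grade	2	3	87	82
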