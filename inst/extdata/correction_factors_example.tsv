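age_band	period	factor
55-59	1989-1992	0.93
60-64	1989-1992	0.91
65-69	1989-1992	0.90
70-74	1989-1992	0.88
75-79	1989-1992	0.86
80-84	1989-1992	0.85
85+	1989-1992	0.83
*	1969-1972	0.95
*	1979-1982	0.95
*	*	1.0
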