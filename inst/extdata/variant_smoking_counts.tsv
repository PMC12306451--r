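variant	comparison	a	b	c	d
rs4388642	CC_ever_vs_TT_never	531	18314	1122	62464
rs4388642	CT_ever_vs_TT_never	1877	82965	1122	62464
rs17562659	CC_ever_vs_TT_never	50	1825	1973	104396
rs17562659	CT_ever_vs_TT_never	836	34342	1973	104396
rs10922273	TT_ever_vs_CC_never	25	1368	2014	107214
rs10922273	CT_ever_vs_CC_never	572	29845	2014	107214
rs10033900	TT_ever_vs_CC_never	1101	44817	667	34843
rs10033900	CT_ever_vs_CC_never	2068	97620	667	34843
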