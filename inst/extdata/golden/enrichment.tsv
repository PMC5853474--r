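category_id	category_name	k	n	K	N	odds_ratio	p_value	adj_p	direction
CAT:PT	mRNA stability pathway	7	9	7	27	Inf	4.0539171e-05	8.1078342e-05	over
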