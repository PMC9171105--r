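attempt_index	first_row	first_col	second_row	second_col	first_sound	second_sound	matched
1	0	0	0	1	bee	lion	FALSE
2	0	0	0	2	bee	frog	FALSE
3	0	1	0	2	lion	frog	FALSE
4	0	0	0	3	bee	bee	TRUE
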