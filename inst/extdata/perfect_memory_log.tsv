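attempt_index	first_row	first_col	second_row	second_col	first_sound	second_sound	matched
1	0	0	0	1	bee	lion	FALSE
2	0	2	0	4	frog	rooster	FALSE
3	0	3	1	0	bee	lion	FALSE
4	0	0	0	3	bee	bee	TRUE
5	0	1	1	0	lion	lion	TRUE
6	1	1	0	2	frog	frog	TRUE
7	1	2	0	4	rooster	rooster	TRUE
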