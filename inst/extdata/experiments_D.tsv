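id	f	speed	fan_pwm	failed	n_base_layers	pass_pattern	pass_f	pass_speed	notes
D1B	0.20	5000	255	FALSE	3	diagonal	0.20	5000	
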