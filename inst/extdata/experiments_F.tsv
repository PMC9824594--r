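id	f	speed	fan_pwm	failed	n_base_layers	pass_pattern	pass_f	pass_speed	notes
F1B	1.00	600	0	FALSE	NA	NA	NA	NA	
F2B	0.60	600	0	FALSE	NA	NA	NA	NA	
F3B	0.45	600	0	FALSE	NA	NA	NA	NA	
F4B	0.30	600	0	FALSE	NA	NA	NA	NA	
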