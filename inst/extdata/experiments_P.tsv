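id	f	speed	fan_pwm	failed	n_base_layers	pass_pattern	pass_f	pass_speed	notes
P1B	0.40	6000	255	FALSE	3	parallel	0.40	6000	
P2B	0.20	600	255	FALSE	3	parallel	0.20	600	
P3B	0.20	4200	255	FALSE	3	parallel	0.20	4200	
P4B	0.20	5000	255	FALSE	3	parallel	0.20	5000	
P5B	0.20	6000	255	FALSE	3	parallel	0.20	6000	
P6B	0.10	600	255	FALSE	3	parallel	0.10	600	
P7B	0.10	4200	255	FALSE	3	parallel	0.10	4200	
P8B	0.10	5000	255	FALSE	3	parallel	0.10	5000	
P9B	0.10	6000	255	FALSE	3	parallel	0.10	6000	
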