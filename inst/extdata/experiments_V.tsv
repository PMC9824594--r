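id	f	speed	fan_pwm	failed	n_base_layers	pass_pattern	pass_f	pass_speed	notes
V1B	0.60	5000	0	FALSE	NA	NA	NA	NA	
V2B	0.60	6000	0	FALSE	NA	NA	NA	NA	
V3B	0.45	1200	0	FALSE	NA	NA	NA	NA	
V4B	0.45	3000	0	FALSE	NA	NA	NA	NA	
V5B	0.45	4200	0	FALSE	NA	NA	NA	NA	
V6B	0.60	5000	0	FALSE	NA	NA	NA	NA	
V7B	0.45	6000	0	FALSE	NA	NA	NA	NA	
V8B	0.30	1200	0	TRUE	NA	NA	NA	NA	first layer did not adhere to the hot bed; no micrograph
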