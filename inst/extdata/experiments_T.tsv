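id	f	speed	fan_pwm	failed	n_base_layers	pass_pattern	pass_f	pass_speed	notes
T1B	0.60	600	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T2B	0.60	5000	150	FALSE	NA	NA	NA	NA	PWM printed as 150 (58.8 %)
T3B	0.60	5000	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T4B	0.45	6000	50	FALSE	NA	NA	NA	NA	PWM printed as 50 (19.6%)
T5B	0.60	6000	150	FALSE	NA	NA	NA	NA	PWM printed as 150 (58.8 %)
T6B	0.60	6000	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T7B	0.45	600	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T8B	0.45	3000	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T9B	0.45	4200	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (100 %)
T10B	0.45	5000	255	FALSE	NA	NA	NA	NA	PWM printed as 255 (19.6%), annotation inconsistent with value
T11B	0.45	6000	50	FALSE	NA	NA	NA	NA	PWM printed as 50 (100 %), annotation inconsistent with value
T12B	0.45	6000	255	TRUE	NA	NA	NA	NA	PWM printed as 255 (19.6%), annotation inconsistent with value; first layer did not adhere; no micrograph
T13B	0.30	600	255	TRUE	NA	NA	NA	NA	PWM printed as 255 (100 %); first layer did not adhere; no micrograph
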