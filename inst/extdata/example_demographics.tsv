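patient_id	age_years	sex	body_weight_kg	interacting_drug
A01	71.2	M	82.5	1
A02	64.8	F	70.1	0
A03	58.3	M	91.0	1
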