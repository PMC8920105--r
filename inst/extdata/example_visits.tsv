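patient_id	t_days	inr	dose_mg	tau_h
A01	0	1.8	5	24
A01	28	2.4	6	24
A01	56	2.6	6	24
A01	84	2.5	6	24
A02	0	3.4	9	24
A02	30	2.9	8	24
A02	62	2.7	8	24
A02	95	2.8	8	24
A03	0	2.1	4.5	24
A03	25	2.3	5	24
A03	55	2.9	5	24
A03	90	2.4	4.5	24
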