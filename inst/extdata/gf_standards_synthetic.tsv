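name	mass_kda	rs_nm	ve_ml
thyroglobulin	670	8.6	8.035
gamma-globulin	158	5.1	11.046
conalbumin	75	3.72	12.6
ovalbumin	44	2.73	13.711
myoglobin	17	1.91	15.694
vitamin B12	1.35	0.85	20.974
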