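measure	electrode	session	mean	sd
amplitude	Fz	1	1.88	2.44
amplitude	Cz	1	2.95	1.99
amplitude	Pz	1	2.45	1.52
amplitude	Fz	5	3.99	4.34
amplitude	Cz	5	4.20	2.92
amplitude	Pz	5	3.00	1.98
curve_difference	Fz	1	2.63	2.14
curve_difference	Cz	1	3.25	2.09
curve_difference	Pz	1	2.85	1.64
curve_difference	Fz	5	5.12	4.20
curve_difference	Cz	5	4.68	3.17
curve_difference	Pz	5	3.66	2.28
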