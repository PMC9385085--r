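session	mental	physical	temporal	performance	effort	frustration	total	raw
1	23.10	0.63	5.74	7.98	18.67	6.62	62.84	50.29
2	18.04	1.31	4.65	6.11	15.69	5.26	51.16	40.92
3	16.45	1.75	6.10	6.03	13.51	5.15	49.08	39.11
4	16.57	1.69	5.39	6.90	14.37	4.08	49.08	38.28
5	19.41	1.54	5.80	9.88	15.09	6.87	58.69	46.61
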