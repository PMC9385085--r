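session	threshold_mean	threshold_sd
1	25.11	7.97
5	20.16	6.77
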