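session	copy_accuracy	copy_sd	dual_accuracy	dual_sd	fz_amp_copy	fz_amp_copy_sd	fz_amp_dual	fz_amp_dual_sd
1	79.2	16.1	69.5	21.5	3.03	3.03	3.98	4.79
5	92.0	10.1	80.3	18.1	5.65	4.67	5.70	6.86
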