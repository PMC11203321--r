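trait	sigma2_g	sigma2_ge	sigma2_e	H2_percent
DTT	13.61	9.22	4.26	82.75
DTP	19.84	10.68	4.29	86.09
DTS	23.98	14.12	4.92	85.26
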