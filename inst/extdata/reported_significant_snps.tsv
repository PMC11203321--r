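model	trait	snp	chrom	pos	bin	p_value	r2_percent
BLINK	DTT	1_190275500	1	190275500	1.06	5.52e-11	1.41
BLINK	DTT	9_152140631	9	152140631	9.07	2.48e-9	16.92
BLINK	DTT	10_146767704	10	146767704	10.07	2.34e-8	1.97
BLINK	DTP	3_198946071	3	198946071	3.07	3.23e-8	2.64
BLINK	DTP	3_229665314	3	229665314	3.09	2.68e-7	3.90
BLINK	DTP	8_114509981	8	114509981	8.04	2.26e-7	3.70
BLINK	DTP	9_152140631	9	152140631	9.07	3.98e-11	12.68
BLINK	DTS	8_78666793	8	78666793	8.03	2.42e-12	3.39
BLINK	DTS	9_152140631	9	152140631	9.07	3.52e-7	24.17
FarmCPU	DTT	3_198946071	3	198946071	3.07	2.52e-8	4.34
FarmCPU	DTT	9_152140631	9	152140631	9.07	7.35e-15	15.53
FarmCPU	DTT	10_149653921	10	149653921	10.07	1.27e-7	3.55
FarmCPU	DTP	3_10537234	3	10537234	3.03	2.67e-8	1.02
FarmCPU	DTP	8_77014638	8	77014638	8.03	2.05e-7	0.50
FarmCPU	DTP	9_18946215	9	18946215	9.02	1.42e-7	3.74
FarmCPU	DTP	9_146646966	9	146646966	9.06	3.90e-9	1.18
FarmCPU	DTP	9_152140631	9	152140631	9.07	8.05e-13	5.82
FarmCPU	DTP	10_145158286	10	145158286	10.07	7.89e-14	3.73
FarmCPU	DTS	3_199485386	3	199485386	3.07	1.35e-7	7.16
FarmCPU	DTS	8_78666793	8	78666793	8.03	8.63e-9	2.30
FarmCPU	DTS	9_146646966	9	146646966	9.06	3.68e-7	3.30
FarmCPU	DTS	9_152140631	9	152140631	9.07	3.40e-9	8.53
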