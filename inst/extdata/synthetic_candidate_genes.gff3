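##gff-version 3
1	synthetic	gene	5000000	5004000	.	+	.	ID=SYNDECOY_FAR1;description=synthetic far decoy
1	synthetic	gene	190261501	190265501	.	+	.	ID=Zm00001d031443;description=synthetic gene model near 1_190275500
1	synthetic	gene	190274000	190278000	.	+	.	ID=Zm00001d031445;description=synthetic gene model near 1_190275500
1	synthetic	gene	190278500	190283500	.	-	.	ID=Zm00001d031444;description=synthetic gene model near 1_190275500
1	synthetic	gene	190285500	190289500	.	-	.	ID=Zm00001d031447;description=synthetic gene model near 1_190275500
1	synthetic	gene	190285501	190288501	.	+	.	ID=SYNDECOY_1_190275500;description=synthetic decoy outside 10 kb window
2	synthetic	gene	1000000	1004000	.	-	.	ID=SYNDECOY_CHR2;description=synthetic far decoy
3	synthetic	gene	10535734	10539734	.	+	.	ID=Zm00001d039650;description=synthetic gene model near 3_10537234
3	synthetic	gene	10547235	10550235	.	+	.	ID=SYNDECOY_3_10537234;description=synthetic decoy outside 10 kb window
3	synthetic	gene	198944571	198948571	.	+	.	ID=Zm00001d043406;description=synthetic gene model near 3_198946071
3	synthetic	gene	198956072	198959072	.	+	.	ID=SYNDECOY_3_198946071;description=synthetic decoy outside 10 kb window
3	synthetic	gene	199483886	199487886	.	+	.	ID=Zm00001d043427;description=synthetic gene model near 3_199485386
3	synthetic	gene	199488386	199493386	.	-	.	ID=Zm00001d043426;description=synthetic gene model near 3_199485386
3	synthetic	gene	199495387	199498387	.	+	.	ID=SYNDECOY_3_199485386;description=synthetic decoy outside 10 kb window
3	synthetic	gene	229663814	229667814	.	+	.	ID=Zm00001d044495;description=synthetic gene model near 3_229665314
3	synthetic	gene	229668314	229673314	.	-	.	ID=Zm00001d044496;description=synthetic gene model near 3_229665314
3	synthetic	gene	229675315	229678315	.	+	.	ID=SYNDECOY_3_229665314;description=synthetic decoy outside 10 kb window
8	synthetic	gene	77013138	77017138	.	+	.	ID=Zm00001d009708;description=synthetic gene model near 8_77014638
8	synthetic	gene	77017638	77022638	.	-	.	ID=Zm00001d009707;description=synthetic gene model near 8_77014638
8	synthetic	gene	77024639	77027639	.	+	.	ID=SYNDECOY_8_77014638;description=synthetic decoy outside 10 kb window
8	synthetic	gene	78665293	78669293	.	+	.	ID=Zm00001d009738;description=synthetic gene model near 8_78666793
8	synthetic	gene	78676794	78679794	.	+	.	ID=SYNDECOY_8_78666793;description=synthetic decoy outside 10 kb window
8	synthetic	gene	114508481	114512481	.	+	.	ID=Zm00001d010425;description=synthetic gene model near 8_114509981
8	synthetic	gene	114519982	114522982	.	+	.	ID=SYNDECOY_8_114509981;description=synthetic decoy outside 10 kb window
9	synthetic	gene	18944715	18948715	.	+	.	ID=Zm00001d045323;description=synthetic gene model near 9_18946215
9	synthetic	gene	18949215	18954215	.	-	.	ID=Zm00001d045324;description=synthetic gene model near 9_18946215
9	synthetic	gene	18956216	18959216	.	+	.	ID=SYNDECOY_9_18946215;description=synthetic decoy outside 10 kb window
9	synthetic	gene	146645466	146649466	.	+	.	ID=Zm00001d047969;description=synthetic gene model near 9_146646966
9	synthetic	gene	146649966	146654966	.	-	.	ID=Zm00001d047968;description=synthetic gene model near 9_146646966
9	synthetic	gene	146656967	146659967	.	+	.	ID=SYNDECOY_9_146646966;description=synthetic decoy outside 10 kb window
9	synthetic	gene	152139131	152143131	.	+	.	ID=Zm00001d048190;description=synthetic gene model near 9_152140631
9	synthetic	gene	152143631	152148631	.	-	.	ID=Zm00001d048191;description=synthetic gene model near 9_152140631
9	synthetic	gene	152150632	152153632	.	+	.	ID=SYNDECOY_9_152140631;description=synthetic decoy outside 10 kb window
10	synthetic	gene	145156786	145160786	.	+	.	ID=Zm00001d026397;description=synthetic gene model near 10_145158286
10	synthetic	gene	145161286	145166286	.	-	.	ID=Zm00001d026396;description=synthetic gene model near 10_145158286
10	synthetic	gene	145168287	145171287	.	+	.	ID=SYNDECOY_10_145158286;description=synthetic decoy outside 10 kb window
10	synthetic	gene	146766204	146770204	.	+	.	ID=Zm00001d026482;description=synthetic gene model near 10_146767704
10	synthetic	gene	146777705	146780705	.	+	.	ID=SYNDECOY_10_146767704;description=synthetic decoy outside 10 kb window
10	synthetic	gene	149652421	149656421	.	+	.	ID=Zm00001d026668;description=synthetic gene model near 10_149653921
10	synthetic	gene	149663922	149666922	.	+	.	ID=SYNDECOY_10_149653921;description=synthetic decoy outside 10 kb window
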