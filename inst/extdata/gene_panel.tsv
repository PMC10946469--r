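# Curated 37-gene panel for monogenic bone disorders: 15 genes of
# dominantly inherited disorders (rarity cutoff 0.001; includes the
# X-linked PLS3 and PHEX, grouped with the dominant cutoff class) and 22
# genes of recessively inherited disorders (cutoff 0.01).
# RECONSTRUCTION NOTE (synthetic coordinates): interval coordinates are
# approximate GRCh37 gene spans transcribed from public genome browsers,
# adequate for CNV-overlap screening, not for base-precise annotation.
symbol	inheritance	chrom	start	end
COL1A1	dominant	17	48260650	48278993
COL1A2	dominant	7	94023873	94060544
IFITM5	dominant	11	299496	301771
SGMS2	dominant	4	108745710	108828343
P4HB	dominant	17	79801034	79818574
LRP5	dominant	11	68080077	68216743
WNT1	dominant	12	49372116	49375648
PLS3	dominant	X	114795465	114885190
CLCN7	dominant	16	1496046	1526248
PLEKHM1	dominant	17	43513266	43568146
TNFRSF11A	dominant	18	59992538	60058515
ALPL	dominant	1	21835858	21904905
PHEX	dominant	X	22032332	22251311
DKK1	dominant	10	54074056	54077416
WNT3A	dominant	1	228194448	228248553
TCIRG1	recessive	11	67806678	67818574
BMP1	recessive	8	22022415	22068047
CRTAP	recessive	3	33155475	33189582
LEPRE1	recessive	1	43212006	43232755
PPIB	recessive	15	64448014	64455587
SERPINH1	recessive	11	75273101	75283788
FKBP10	recessive	17	39968745	39979473
SERPINF1	recessive	17	1665244	1680878
SP7	recessive	12	53720500	53739252
TMEM38B	recessive	9	108456832	108528329
CREB3L1	recessive	11	46299206	46342972
SPARC	recessive	5	151040657	151066726
TENT5A	recessive	6	82454539	82461434
PLOD2	recessive	3	145787740	145878955
SEC24D	recessive	4	119631670	119759752
CTSK	recessive	1	150768684	150780915
XYLT2	recessive	17	48423380	48438550
MESD	recessive	15	81296146	81316220
KDELR2	recessive	7	6486557	6507147
CCDC134	recessive	22	42196747	42222097
DMP1	recessive	4	88583454	88597224
ENPP1	recessive	6	132129151	132216295
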