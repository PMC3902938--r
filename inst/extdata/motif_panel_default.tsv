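name	motif	target_region	scoring
Puf3_3utr	CYUGUAAAUA	utr3	count
Puf4_3utr	UGUAHAUA	utr3	count
Puf5_3utr	UGUAAYAUA	utr3	count
Puf6_3utr	UGUANAUA	utr3	count
Puf1_3utr	UAAUAAU	utr3	count
Puf2_3utr	UAAURAU	utr3	count
Pab1_3utr	AAAAAAA	utr3	count
Pub1_3utr	UUUUUA	utr3	count
Vts1_3utr	CUGGC	utr3	count
Hrp1_3utr	UAUAUA	utr3	count
Whi3_3utr	UGCAU	utr3	count
Cth2_3utr	UAUUUAUU	utr3	count
Pin4_3utr	UGUAUU	utr3	count
Mrn1_3utr	AUACUCC	utr3	count
Slf1_3utr	AAUAAA	utr3	count
Ngr1_3utr	UGUAGU	utr3	count
Nrd1_5utr	GUAAG	utr5	count
Nab3_5utr	UCUUG	utr5	count
Ssd1_5utr	CNYUCNYU	utr5	count
Nsr1_5utr	GGAGG	utr5	count
Sgn1_5utr	GCUUGC	utr5	count
Npl3_5utr	GGAGU	utr5	count
Khd1_orf	CAACAAC	orf	count
She2_orf	CGACG	orf	count
Gis2_orf	GAUGAU	orf	count
Scp160_orf	CCUCCU	orf	count
Bfr1_orf	ACCACC	orf	count
Sbp1_orf	GGUGGU	orf	count
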