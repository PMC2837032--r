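# Top 20 annotated transcripts down- and upregulated after photoinduction in a
# two-library Physarum polycephalum sporulation transcriptome survey.
# Library totals: n_d = 125456 (competent), n_l = 99632 (light-induced).
# group = printed table direction; printed_order = row rank within its table.
contig_id	accession	description	hits_d	hits_l	group	printed_order
contig10338_1	P36618	Cell division control protein 16, CDC16	40	1	down	1
contig10470_1	P20072	Annexin A7	68	2	down	2
contig00397_1	Q5BMR2	Phospholipase D (PLD1)	62	2	down	3
contig00525_1	Q7EYV7	Poly ADP-ribose polymerase 1 (PARP-1)	244	10	down	4
contig11321_1	P38750	Uncharacterized transporter YHL008C	24	1	down	5
contig00901_1	P16064	Subtilisin inhibitor 1, ASI-I	21	1	down	6
PpolyN1a03a12	Q07346	Glutamate decarboxylase, GAD	20	1	down	7
PpolyN1a02c07	P34121	Coactosin, coaA	56	3	down	8
contig11574_1	P39749	Flap endonuclease 1, FEN-1	18	1	down	9
contig10414_1	Q5UNX2	Putative ankyrin repeat protein, YL715	90	5	down	10
contig03548_1	O49286	F-box/LRR-repeat protein 5, FBL5	17	1	down	11
contig00369_1	Q80U58	Pumilio homolog 2	17	1	down	12
contig10457_1	Q8WN03	Kv channel-interacting protein 2, Kcnip2	16	1	down	13
contig00264_1	P13466	Actin-binding protein 120, ABP-120	32	2	down	14
contig02333_1	Q8RWN7	POLTERGEIST Protein phosphatase 2C 32, PP2C	15	1	down	15
contig01650_1	O24496	Glyoxalase II, Glx II	15	1	down	16
contig01322_1	Q94B74	NADH pyrophosphatase	15	1	down	17
contig08310_1	Q10MW3	Pyruvate decarboxylase isozyme 2, PDC2	73	5	down	18
contig00558_1	P18281	Actobindin	29	2	down	19
contig11873_1	O10296	Apoptosis inhibitor 1, IAP-1	28	2	down	20
PpolyN1d39e07	O08623	Sequestosome-1, SQSTM1	3	171	up	1
contig02685_1	Q54IV3	ATP-dependent RNA helicase, DDX42	1	37	up	2
PpolyN1d106h10	Q9U1K1	Spire	23	813	up	3
PpolyN1a08g07	O08849	Regulator of G-protein signaling 2, RGS2	1	22	up	4
contig05590_1	Q8H100	ADP-ribosylation factor GTPase-activating, AGD8	1	21	up	5
PpolyN1a14d12	Q07283	Trichohyalin, TRHY	1	20	up	6
contig11781_1	Q55D99	Serine/threonine-protein kinase, pakA	2	34	up	7
contig06420_1	Q9UUG5	Myosin regulatory light chain 1, MLR1	1	17	up	8
contig08470_1	Q54MI7	Uncharacterized protein DDB_G0285917	1	16	up	9
contig12553_1	Q5R826	Transmembrane protein 63A, TM63A	20	308	up	10
PpolyN1d18d06	Q05924	Dosage-dependent cell cycle regulator 2, DCR2	1	15	up	11
contig08799_1	Q43207	Rotamase, FKBP70	1	14	up	12
contig12445_1	Q7S045	Non-histone chromosomal protein 6, NHP6	1	13	up	13
contig11110_1	P54678	Calcium-transporting ATPase, PAT1	1	13	up	14
contig08929_1	Q39572	Ras-related YPTC6	1	13	up	15
contig08360_1	Q6TQE1	Zinc finger-containing protein 18, NHN1	1	12	up	16
contig04102_1	Q9D0C1	Rab RING finger 7, RR7	4	47	up	17
contig03233_1	P06704	Cell division control protein 31, CDC31	2	23	up	18
contig02500_1	Q5UPW6	Putative FNIP repeat-containing protein, L281	2	23	up	19
contig08917_1	Q9PTW9	Proteasome subunit alpha type-7, PSMA7	1	11	up	20
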