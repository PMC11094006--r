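pathway_id	name	kos
WL	Wood-Ljungdahl pathway	K00198,K05299,K15022,K01938,K01491,K00297,K15023,K14138,K00197,K00194
DC4HB	Dicarboxylate/4-hydroxybutyrate cycle	K01964,K15036,K15037,K15016,K14465,K14467
HP4HB	3-Hydroxypropionate/4-hydroxybutyrate cycle	K01007,K01595,K15039,K15017,K15018,K15019
MCR	Methyl-coenzyme M reductase	K00399,K00401,K00402
DSR	Dissimilatory sulfate reduction	K00958,K00394,K00395,K11180,K11181
AMO	Ammonia oxidation	K10944,K10945,K10946
ACS	Acetate oxidation (acetyl-CoA synthetase)	K01895
PTA_ACK	Phosphate acetyltransferase-acetate kinase	K00625,K00925
SQR	Sulfide oxidation (sulfide:quinone oxidoreductase)	K17218
URE	Urea hydrolysis	K01428,K01429,K01430
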