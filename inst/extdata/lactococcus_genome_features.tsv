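strain	species	scaffold_count	size_mb	gc_percent	coding_genes	accession
DSM 22330	Lactococcus chungangensis	86	2.20	38.67	2154	JXJT00000000
DSM 20684	Lactococcus garvieae	71	2.02	38.52	1995	JXJV00000000
JCM 16395	Lactococcus fujiensis	69	2.08	36.95	2057	JXJU00000000
ATCC 19257	Lactococcus lactis subsp. cremoris	226	2.32	35.55	2477	JXJZ00000000
DSM 20450	Lactococcus lactis subsp. hordniae	101	2.43	34.81	2684	JXKA00000000
ATCC 19435	Lactococcus lactis subsp. lactis	76	2.46	35.23	2500	JXKB00000000
DSM 21502	Lactococcus lactis subsp. tructae	61	2.61	35.49	2612	JXKC00000000
DSM 6634	Lactococcus piscium	74	2.41	38.55	2301	JXJW00000000
DSM 20686	Lactococcus plantarum	43	1.99	36.76	1861	JXJX00000000
ATCC 43920	Lactococcus raffinolactis	121	2.21	39.67	2143	JXJY00000000
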