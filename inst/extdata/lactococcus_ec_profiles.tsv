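# Curated enzyme inventories (synthetic reconstruction): per-strain presence of the
# carbohydrate-pathway enzymes reported for the ten Lactococcus type strains.
# One row per (gene, genome, EC); gene IDs are synthetic placeholders.
gene_id	genome_id	ec_number
DSM22330_frk	DSM 22330	EC 2.7.1.4
DSM22330_ptsP	DSM 22330	EC 2.7.1.199
DSM22330_pgi	DSM 22330	EC 5.3.1.9
DSM22330_sacA	DSM 22330	EC 3.2.1.26
DSM20684_frk	DSM 20684	EC 2.7.1.4
DSM20684_ptsP	DSM 20684	EC 2.7.1.199
DSM20684_pgi	DSM 20684	EC 5.3.1.9
DSM20684_lacZ	DSM 20684	EC 3.2.1.23
DSM20684_lacE	DSM 20684	EC 2.7.1.207
DSM20684_lacG	DSM 20684	EC 3.2.1.85
DSM20684_rbsK	DSM 20684	EC 2.7.1.15
JCM16395_frk	JCM 16395	EC 2.7.1.4
JCM16395_ptsP	JCM 16395	EC 2.7.1.199
JCM16395_pgi	JCM 16395	EC 5.3.1.9
JCM16395_rbsK	JCM 16395	EC 2.7.1.15
ATCC19257_frk	ATCC 19257	EC 2.7.1.4
ATCC19257_ptsP	ATCC 19257	EC 2.7.1.199
ATCC19257_pgi	ATCC 19257	EC 5.3.1.9
ATCC19257_lacZ	ATCC 19257	EC 3.2.1.23
ATCC19257_lacE	ATCC 19257	EC 2.7.1.207
ATCC19257_lacG	ATCC 19257	EC 3.2.1.85
ATCC19257_rbsK	ATCC 19257	EC 2.7.1.15
DSM20450_frk	DSM 20450	EC 2.7.1.4
DSM20450_ptsP	DSM 20450	EC 2.7.1.199
DSM20450_pgi	DSM 20450	EC 5.3.1.9
DSM20450_sacA	DSM 20450	EC 3.2.1.26
DSM20450_lacZ	DSM 20450	EC 3.2.1.23
DSM20450_lacE	DSM 20450	EC 2.7.1.207
DSM20450_lacG	DSM 20450	EC 3.2.1.85
ATCC19435_frk	ATCC 19435	EC 2.7.1.4
ATCC19435_ptsP	ATCC 19435	EC 2.7.1.199
ATCC19435_pgi	ATCC 19435	EC 5.3.1.9
ATCC19435_lacZ	ATCC 19435	EC 3.2.1.23
ATCC19435_lacE	ATCC 19435	EC 2.7.1.207
ATCC19435_lacG	ATCC 19435	EC 3.2.1.85
ATCC19435_rbsK	ATCC 19435	EC 2.7.1.15
DSM21502_frk	DSM 21502	EC 2.7.1.4
DSM21502_ptsP	DSM 21502	EC 2.7.1.199
DSM21502_pgi	DSM 21502	EC 5.3.1.9
DSM21502_sacA	DSM 21502	EC 3.2.1.26
DSM21502_melA	DSM 21502	EC 3.2.1.22
DSM21502_rbsK	DSM 21502	EC 2.7.1.15
DSM6634_frk	DSM 6634	EC 2.7.1.4
DSM6634_ptsP	DSM 6634	EC 2.7.1.199
DSM6634_pgi	DSM 6634	EC 5.3.1.9
DSM6634_sacA	DSM 6634	EC 3.2.1.26
DSM6634_melA	DSM 6634	EC 3.2.1.22
DSM6634_lacZ	DSM 6634	EC 3.2.1.23
DSM6634_lacE	DSM 6634	EC 2.7.1.207
DSM6634_lacG	DSM 6634	EC 3.2.1.85
DSM6634_rbsK	DSM 6634	EC 2.7.1.15
DSM20686_frk	DSM 20686	EC 2.7.1.4
DSM20686_ptsP	DSM 20686	EC 2.7.1.199
DSM20686_pgi	DSM 20686	EC 5.3.1.9
DSM20686_sacA	DSM 20686	EC 3.2.1.26
ATCC43920_frk	ATCC 43920	EC 2.7.1.4
ATCC43920_ptsP	ATCC 43920	EC 2.7.1.199
ATCC43920_pgi	ATCC 43920	EC 5.3.1.9
ATCC43920_sacA	ATCC 43920	EC 3.2.1.26
ATCC43920_melA	ATCC 43920	EC 3.2.1.22
ATCC43920_lacZ	ATCC 43920	EC 3.2.1.23
ATCC43920_lacE	ATCC 43920	EC 2.7.1.207
ATCC43920_lacG	ATCC 43920	EC 3.2.1.85
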