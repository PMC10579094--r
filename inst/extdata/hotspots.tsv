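gene	protein_change	chrom	pos	ref	alt
KRAS	G12A	chr12	25245350	C	G
KRAS	G12C	chr12	25245351	C	A
KRAS	G12D	chr12	25245350	C	T
KRAS	G12V	chr12	25245350	C	A
KRAS	G12R	chr12	25245351	C	G
KRAS	G12S	chr12	25245351	C	T
KRAS	G13D	chr12	25245347	C	T
KRAS	Q61H	chr12	25227341	T	G
KRAS	Q61L	chr12	25227342	T	A
KRAS	Q61R	chr12	25227342	T	C
NRAS	G12D	chr1	114716126	C	T
NRAS	G13D	chr1	114716123	C	T
NRAS	Q61K	chr1	114713909	G	T
NRAS	Q61L	chr1	114713908	T	A
NRAS	Q61R	chr1	114713908	T	C
BRAF	V600E	chr7	140753336	A	T
EGFR	L858R	chr7	55191822	T	G
EGFR	T790M	chr7	55181378	C	T
PIK3CA	E542K	chr3	179218294	G	A
PIK3CA	E545K	chr3	179218303	G	A
PIK3CA	H1047R	chr3	179234297	A	G
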