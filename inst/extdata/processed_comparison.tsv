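accession	gene	description	sc_ref	abun_ref	sc_cmp	abun_cmp	nsaf_ratio	expression
O75969	AKAP3	A-kinase anchor protein 3	146.3	H	81.7	H	0.56	UE
O96005	CLPTM1	Cleft lip and palate transmembrane protein 1	41.3	M	19.0	L	0.45	UE
Q9Y619	SLC25A15	Mitochondrial ornithine transporter 1	26.0	M	12.0	L	0.47	UE
Q8TF71	SLC16A10	Monocarboxylate transporter 10	2.0	VL	0.0	-	0.00	Unique to group_ref
Q96ND0	FAM210A	Protein FAM210A	5.0	VL	0.7	VL	0.14	UE
P12074	COX6A1	Cytochrome c oxidase subunit 6A1, mitochondrial	10.0	L	21.0	M	2.15	OE
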