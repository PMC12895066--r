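protein_md5	protein_seq	og_id	level	kegg_ko	kegg_pathway	ec	go	cog_category
2280c44d9706fc136157fb850a758466		OG0001	Bacteria	K00001	map00020		GO:0000013	P
994d1a1c86b9dd99c52d90e2c7db24e8		OG0002	Bacteria	K00002	map00080	1.8.6.13	GO:0000026	GK
0a0df9a9631813e3df840d2af57f5288		OG0003	Bacteria	K00003	map00040		GO:0000039	CK
c45447efbe28099d5715898b15d396db		OG0004	Bacteria	K00004	map00080	2.9.4.65	GO:0000052	KL
4d7ac0f1e7c83636484f5065502574a4		OG0005	Bacteria	K00005	map00060		GO:0000065	KL
5259880ff33363dbd0e350f6aa2c8bcd		OG0017	Bacteria	K00017	map00010		GO:0000221	E
	MDSYMWGLKEKTQVCFNSKSIQFPEQDHCPMCIVAHCQMKRLLERFSVWAYKSMRGRCQNLLANSANVYSRDTISFRKRHRFLDYEG	OG0010	Bacteria	K00010	map00030	5.1.8.29	GO:0000130	CE
649691c7c4cd62f19e34a5b5917d430b		OG0006	Bacteria	K00006	map00050	2.2.1.5	GO:0000078	PE
890c54267d064613094ae332fad55993		OG0009	Bacteria	K00009	map00030		GO:0000117	TJ
8fcde689fad6706ec4690966ea58c0b9		OG0008	Bacteria	K00008	map00040	5.7.4.30	GO:0000104	JL
d71900b05f6c8ede877335ec5db1e5a6		OG0024	Bacteria	K00024	map00040	1.1.6.13	GO:0000312	CE
253d97427cf1e8b6fa916f636598b305		OG0020	Bacteria	K00020	map00040	2.8.7.47	GO:0000260	T
aed2159430a4cd7456e9c5bccc293072		OG0001	Bacteria	K00001	map00020		GO:0000013	P
	MGWQFENDNNRFMRVYTKPMDHRWSVGAQPYWPITFFYRIPHQHAFMSMFNMYATFQFKWKLNFYQEQWCLDGMAHWPSQCRYL	OG0002	Bacteria	K00002	map00080	1.8.6.13	GO:0000026	GK
757516ffb9ffa19711daf8130fc9d752		OG0003	Bacteria	K00003	map00040		GO:0000039	CK
04da8e35fdbf64845d34c258992e2d0b		OG0004	Bacteria	K00004	map00080	2.9.4.65	GO:0000052	KL
706c43434435081d95fb17d117cc34ee		OG0005	Bacteria	K00005	map00060		GO:0000065	KL
5c2df51dce44cc5337d0f69bd945fcd9		OG0016	Bacteria	K00016	map00040	2.8.9.20	GO:0000208	E
bf77f86a08da2c5dff6a855e16a49e88		OG0021	Bacteria	K00021	map00010		GO:0000273	TH
3d6962359fa2686340bf3237bec558f1		OG0007	Bacteria	K00007	map00020		GO:0000091	L
	MSQWKHDAQWLRAWAVEESKRDEDRMRCGSNSHPTDEPMKPEEKTEYLTVGKLCQCCHIQKADHGETCNTKPLEQV	OG0006	Bacteria	K00006	map00050	2.2.1.5	GO:0000078	PE
4934afe2826f6357f1bb01891cc62020		OG0022	Bacteria	K00022	map00020	6.5.2.11	GO:0000286	T
5650c0b8a4a434095b717f0f51df55e8		OG0015	Bacteria	K00015	map00060		GO:0000195	C
ab271b78034ad7844ea5c512f08f0155		OG0012	Bacteria	K00012	map00050	5.6.9.68	GO:0000156	L
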