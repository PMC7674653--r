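strain	position	size	locus_tag	product
A	341278-349235	7.96 kb	X276_25195	DNA-3-methyladenine glycosylase 2 family protein
A	341278-349235	7.96 kb	X276_25190	Site-specific integrase
A	341278-349235	7.96 kb	X276_25185	XRE family transcriptional regulator
A	341278-349235	7.96 kb	X276_25180	Hypothetical protein
A	341278-349235	7.96 kb	X276_25175	Transcription factor
A	341278-349235	7.96 kb	X276_25170	Hypothetical protein
A	341278-349235	7.96 kb	X276_25165	Replication protein
A	341278-349235	7.96 kb	X276_25160	Hypothetical protein
A	341278-349235	7.96 kb	X276_25155	Hypothetical protein
A	341278-349235	7.96 kb	X276_25150	Hypothetical protein
A	341278-349235	7.96 kb	X276_25145	Hypothetical protein
B	341243-349259	8.02 kb	X276_25195	DNA-3-methyladenine glycosylase 2 family protein
B	341243-349259	8.02 kb	X276_25190	Site-specific integrase
B	341243-349259	8.02 kb	X276_25185	XRE family transcriptional regulator
B	341243-349259	8.02 kb	X276_25180	Hypothetical protein
B	341243-349259	8.02 kb	X276_25175	Transcription factor
B	341243-349259	8.02 kb	X276_25170	Hypothetical protein
B	341243-349259	8.02 kb	X276_25165	Replication protein
B	341243-349259	8.02 kb	X276_25160	Hypothetical protein
B	341243-349259	8.02 kb	X276_25155	Hypothetical protein
B	341243-349259	8.02 kb	X276_25150	Hypothetical protein
B	341243-349259	8.02 kb	X276_25145	Hypothetical protein
C	341297-349217	7.92 kb	X276_25195	DNA-3-methyladenine glycosylase 2 family protein
C	341297-349217	7.92 kb	X276_25190	Site-specific integrase
C	341297-349217	7.92 kb	X276_25185	XRE family transcriptional regulator
C	341297-349217	7.92 kb	X276_25180	Hypothetical protein
C	341297-349217	7.92 kb	X276_25175	Transcription factor
C	341297-349217	7.92 kb	X276_25170	Hypothetical protein
C	341297-349217	7.92 kb	X276_25165	Replication protein
C	341297-349217	7.92 kb	X276_25160	Hypothetical protein
C	341297-349217	7.92 kb	X276_25155	Hypothetical protein
C	341297-349217	7.92 kb	X276_25150	Hypothetical protein
C	341297-349217	7.92 kb	X276_25145	Hypothetical protein
B33	167230-167409	180 bp	X276_26025	PIN/TRAM domain-containing protein
B33	499439-499573	135 bp		Only intergenic
B33	575045-575230	186 bp		Only intergenic
B33	728816-728957	142 bp	X276_23400	Hypothetical protein
B33	6042705-6042895	191 bp	X276_00695	Methyl-accepting chemotaxis protein
B33	6137871-6138337	467 bp	X276_00305	23S rRNA [pseudouridine(1915)-N(3)]-methyltransferase RlmH
B44	341237-349270	8.03 kb	X276_25195	DNA-3-methyladenine glycosylase 2 family protein
B44	341237-349270	8.03 kb	X276_25190	Site-specific integrase
B44	341237-349270	8.03 kb	X276_25185	XRE family transcriptional regulator
B44	341237-349270	8.03 kb	X276_25180	Hypothetical protein
B44	341237-349270	8.03 kb	X276_25175	Transcription factor
B44	341237-349270	8.03 kb	X276_25170	Hypothetical protein
B44	341237-349270	8.03 kb	X276_25165	Replication protein
B44	341237-349270	8.03 kb	X276_25160	Hypothetical protein
B44	341237-349270	8.03 kb	X276_25155	Hypothetical protein
B44	341237-349270	8.03 kb	X276_25150	Hypothetical protein
B44	341237-349270	8.03 kb	X276_25145	Hypothetical protein
E15	4901-5166	266 bp	X276_26795	DNA topoisomerase (ATP-hydrolyzing) subunit B
E28	341278-349256	7.98 kb	X276_25195	DNA-3-methyladenine glycosylase 2 family protein
E28	341278-349256	7.98 kb	X276_25190	Site-specific integrase
E28	341278-349256	7.98 kb	X276_25185	XRE family transcriptional regulator
E28	341278-349256	7.98 kb	X276_25180	Hypothetical protein
E28	341278-349256	7.98 kb	X276_25175	Transcription factor
E28	341278-349256	7.98 kb	X276_25170	Hypothetical protein
E28	341278-349256	7.98 kb	X276_25165	Replication protein
E28	341278-349256	7.98 kb	X276_25160	Hypothetical protein
E28	341278-349256	7.98 kb	X276_25155	Hypothetical protein
E28	341278-349256	7.98 kb	X276_25150	Hypothetical protein
E28	341278-349256	7.98 kb	X276_25145	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25190	Site-specific integrase
E33	341393-349134	7.74 kb	X276_25185	XRE family transcriptional regulator
E33	341393-349134	7.74 kb	X276_25180	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25175	Transcription factor
E33	341393-349134	7.74 kb	X276_25170	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25165	Replication protein
E33	341393-349134	7.74 kb	X276_25160	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25155	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25150	Hypothetical protein
E33	341393-349134	7.74 kb	X276_25145	Hypothetical protein
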