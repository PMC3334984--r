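pool	accession	platform	read_length	read_count_million	coverage	excluded
1	Armking	illumina	94	5.85	2.42	FALSE
1	Big Top	illumina	94	3.55	1.47	FALSE
1	Fidelia	illumina	94	6.47	2.68	FALSE
1	Flordastar	illumina	94	7.27	3.01	FALSE
1	Silver Rome	illumina	94	8.35	3.45	FALSE
1	Weinberger	illumina	94	9.72	4.02	FALSE
2	Babygold 8	illumina	93	5.60	2.29	FALSE
2	Elberta	illumina	93	5.63	2.30	FALSE
2	Maruja	illumina	93	8.52	3.49	FALSE
2	Maycrest	illumina	93	8.61	3.52	FALSE
2	Oro A	illumina	93	7.20	2.95	FALSE
2	Stark Red Gold	illumina	93	6.37	2.61	FALSE
3	Circe	illumina	93	9.23	3.78	FALSE
3	Imera	illumina	93	5.92	2.42	FALSE
3	Percoca di Romagna 7	illumina	93	4.27	1.75	FALSE
3	Pillar	illumina	93	1.40	0.57	FALSE
3	S 2678	illumina	93	10.15	4.15	FALSE
3	Stark Saturn	illumina	93	7.45	3.05	FALSE
4	Kamarat	illumina	93	9.63	3.94	FALSE
4	Leonforte 1	illumina	93	2.32	0.95	FALSE
4	Sahua Hong Pantao	illumina	93	19.20	7.86	FALSE
4	Shen Zhou Mitao	illumina	93	12.54	5.13	FALSE
4	Tabacchiera	illumina	93	0.56	0.23	FALSE
4	Tudia	illumina	93	7.43	3.04	FALSE
5	GF677	illumina	93	9.22	3.77	FALSE
5	Kurakata Wase	illumina	93	6.75	2.76	FALSE
5	Quetta	illumina	93	12.76	5.22	FALSE
5	S6699	illumina	93	4.90	2.01	FALSE
6	Admiral Dewey	illumina	80	2.42	0.85	FALSE
6	Babcock	illumina	80	3.19	1.12	FALSE
6	Elberta	illumina	80	0.64	0.23	FALSE
6	Slappey	illumina	80	2.02	0.71	FALSE
7	Bolinha	illumina	80	3.55	1.25	FALSE
7	Carmen	illumina	80	1.66	0.58	FALSE
7	Chinese Cling	illumina	80	2.50	0.88	FALSE
7	Mayflower	illumina	80	1.35	0.47	FALSE
8	Diamante	illumina	80	2.11	0.74	FALSE
8	J.H. Hale	illumina	80	3.18	1.12	FALSE
8	Rio Oso Gem	illumina	80	2.57	0.91	FALSE
8	Yellow St. John	illumina	80	1.35	0.48	FALSE
9	Dixon	illumina	80	1.25	0.44	FALSE
9	Early Crawford	illumina	80	3.89	1.37	FALSE
9	Florida Prince	illumina	80	1.85	0.65	FALSE
9	Nonpareil	illumina	80	2.52	0.89	FALSE
10	Dr. Davis	illumina	80	2.31	0.81	FALSE
10	Nemaguard	illumina	80	2.38	0.84	FALSE
10	O'Henry	illumina	80	4.28	1.51	FALSE
10	Okinawa	illumina	80	2.15	0.76	FALSE
11	Georgia Belle	illumina	80	14.42	5.08	FALSE
11	Lovell	illumina	80	6.55	2.30	FALSE
11	Lovell	illumina	80	0.03	0.01	TRUE
11	Oldmixon Free	illumina	80	3.26	1.15	FALSE
12	Big Top	454	330	0.20	0.29	FALSE
12	Binaced	454	355	0.16	0.26	FALSE
12	Catherina	454	288	0.17	0.22	FALSE
12	Elegant Lady	454	243	0.19	0.20	FALSE
12	Nectaross	454	275	0.19	0.23	FALSE
12	O'Henry	454	289	0.15	0.18	FALSE
12	Sweet Cap	454	251	0.16	0.18	FALSE
12	Venus	454	278	0.15	0.19	FALSE
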