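culture_id	colony_id	genotype	foa	nat	hyg	trp	nat_zyg	trp1_zyg	tyr1_alleles
1	1	wildtype_like	+	+	+	+	het	het	both
2	2	wildtype_like	+	-	+	+	hom	het	1
3	3	wildtype_like	+	-	-	-	hom	hom	1
4	4	wildtype_like	+	-	-	-	hom	hom	1
5	5	wildtype_like	+	-	-	-	hom	hom	1
6	6	wildtype_like	+	-	-	-	hom	hom	1
7	7	wildtype_like	+	+	+	+	het	het	both
8	8	wildtype_like	+	+	+	+	het	het	both
9	9	wildtype_like	+	-	-	-	hom	hom	1
10	10	wildtype_like	+	-	-	-	hom	hom	1
11	11	wildtype_like	+	+	+	+	het	het	both
12	12	wildtype_like	+	-	-	-	hom	hom	1
13	13	wildtype_like	+	+	+	+	het	het	both
14	14	wildtype_like	+	-	+	+	hom	het	1
15	15	wildtype_like	+	-	-	-	hom	hom	1
16	16	wildtype_like	+	+	+	+	het	het	both
17	17	wildtype_like	+	+	+	+	het	het	both
18	18	wildtype_like	+	-	-	-	hom	hom	1
19	19	wildtype_like	+	-	+	+	hom	het	1
20	20	wildtype_like	+	+	+	+	het	het	both
21	21	wildtype_like	+	+	+	+	het	het	both
22	22	wildtype_like	+	+	+	+	het	het	both
23	23	wildtype_like	+	+	+	+	het	het	both
24	24	wildtype_like	+	+	+	+	het	het	both
25	25	wildtype_like	+	+	-	-	het	hom	both
26	26	wildtype_like	+	-	-	-	hom	hom	1
27	27	wildtype_like	+	+	+	+	het	het	both
28	28	wildtype_like	+	-	-	-	hom	hom	1
29	29	wildtype_like	+	+	+	+	het	het	both
30	30	wildtype_like	+	+	+	+	het	het	both
31	31	wildtype_like	+	+	+	+	het	het	both
32	32	wildtype_like	+	-	+	+	hom	het	1
33	33	wildtype_like	+	+	+	+	het	het	both
34	34	wildtype_like	+	-	-	-	hom	hom	1
35	35	wildtype_like	+	-	-	-	hom	hom	1
36	36	wildtype_like	+	-	-	-	hom	hom	1
37	37	wildtype_like	+	+	+	+	het	het	both
38	38	wildtype_like	+	-	-	-	hom	hom	1
39	39	wildtype_like	+	+	+	+	het	het	both
40	40	wildtype_like	+	+	+	+	het	het	both
41	41	wildtype_like	+	+	-	-	het	hom	both
42	42	wildtype_like	+	+	+	+	het	het	both
43	43	wildtype_like	+	+	+	+	het	het	both
44	44	wildtype_like	+	-	-	-	hom	hom	1
45	45	wildtype_like	+	+	+	+	het	het	both
46	46	wildtype_like	+	+	-	-	het	hom	both
47	47	wildtype_like	+	-	-	-	hom	hom	1
48	48	wildtype_like	+	+	-	-	het	hom	both
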