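no	ec_number	enzyme
1	EC 1.1.1.1	Alcohol dehydrogenase
2	EC 1.1.1.27	L-lactate dehydrogenase
3	EC 1.1.1.44	6-phosphogluconate dehydrogenase, decarboxylating
4	EC 1.1.1.49	Glucose-6-phosphate 1-dehydrogenase
5	EC 1.2.1.12	glyceraldehyde-3-phosphate dehydrogenase
6	EC 1.2.4.1	pyruvate dehydrogenase E1 component
7	EC 1.2.7.1	Pyruvate-flavodoxin oxidoreductase
8	EC 1.8.1.4	dihydrolipoamide dehydrogenase
9	EC 2.2.1.1	Transketolase
10	EC 2.3.1.12	Dihydrolipoamide acetyltransferase
11	EC 2.7.1.11	6-phosphofructokinase
12	EC 2.7.1.2	Glucokinase
13	EC 2.7.1.40	pyruvate kinase
14	EC 2.7.1.40	Pyruvate kinase
15	EC 2.7.2.3	Phosphoglycerate kinase
16	EC 2.7.6.1	Ribose-phosphate pyrophosphokinase
17	EC 3.1.1.31	6-phosphogluconolactonase
18	EC 3.1.3.11	Fructose-1,6-bisphosphatase
19	EC 3.2.1.86	6-phospho-beta-glucosidase
20	EC 4.1.2.13	Fructose-bisphosphate aldolase class II
21	EC 4.2.1.11	Enolase
22	EC 5.1.3.1	Ribulose-phosphate 3-epimerase
23	EC 5.1.3.3	Aldose 1-epimerase
24	EC 5.3.1.1	Triosephosphate isomerase
25	EC 5.3.1.6	Ribose 5-phosphate isomerase A
26	EC 5.3.1.9	Glucose-6-phosphate isomerase
27	EC 5.4.2.11	2,3-bisphosphoglycerate-dependent phosphoglycerate mutase
28	EC 5.4.2.7	Phosphopentomutase
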