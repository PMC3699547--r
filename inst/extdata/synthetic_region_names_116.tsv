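label	name
1	frontal_01_L
2	frontal_01_R
3	frontal_02_L
4	frontal_02_R
5	frontal_03_L
6	frontal_03_R
7	frontal_04_L
8	frontal_04_R
9	frontal_05_L
10	frontal_05_R
11	frontal_06_L
12	frontal_06_R
13	frontal_07_L
14	frontal_07_R
15	frontal_08_L
16	frontal_08_R
17	precentral_01_L
18	precentral_01_R
19	precentral_02_L
20	precentral_02_R
21	cingulate_01_L
22	cingulate_01_R
23	cingulate_02_L
24	cingulate_02_R
25	cingulate_03_L
26	cingulate_03_R
27	insula_01_L
28	insula_01_R
29	temporal_01_L
30	temporal_01_R
31	temporal_02_L
32	temporal_02_R
33	temporal_03_L
34	temporal_03_R
35	temporal_04_L
36	temporal_04_R
37	temporal_05_L
38	temporal_05_R
39	temporal_06_L
40	temporal_06_R
41	parietal_01_L
42	parietal_01_R
43	parietal_02_L
44	parietal_02_R
45	parietal_03_L
46	parietal_03_R
47	parietal_04_L
48	parietal_04_R
49	parietal_05_L
50	parietal_05_R
51	occipital_01_L
52	occipital_01_R
53	occipital_02_L
54	occipital_02_R
55	occipital_03_L
56	occipital_03_R
57	occipital_04_L
58	occipital_04_R
59	occipital_05_L
60	occipital_05_R
61	subcortical_01_L
62	subcortical_01_R
63	subcortical_02_L
64	subcortical_02_R
65	subcortical_03_L
66	subcortical_03_R
67	subcortical_04_L
68	subcortical_04_R
69	subcortical_05_L
70	subcortical_05_R
71	subcortical_06_L
72	subcortical_06_R
73	limbic_01_L
74	limbic_01_R
75	limbic_02_L
76	limbic_02_R
77	limbic_03_L
78	limbic_03_R
79	limbic_04_L
80	limbic_04_R
81	sensorimotor_01_L
82	sensorimotor_01_R
83	sensorimotor_02_L
84	sensorimotor_02_R
85	sensorimotor_03_L
86	sensorimotor_03_R
87	sensorimotor_04_L
88	sensorimotor_04_R
89	sensorimotor_05_L
90	sensorimotor_05_R
91	cerebellum_01_L
92	cerebellum_01_R
93	cerebellum_02_L
94	cerebellum_02_R
95	cerebellum_03_L
96	cerebellum_03_R
97	cerebellum_04_L
98	cerebellum_04_R
99	cerebellum_05_L
100	cerebellum_05_R
101	cerebellum_06_L
102	cerebellum_06_R
103	cerebellum_07_L
104	cerebellum_07_R
105	cerebellum_08_L
106	cerebellum_08_R
107	cerebellum_09_L
108	cerebellum_09_R
109	vermis_01
110	vermis_02
111	vermis_03
112	vermis_04
113	vermis_05
114	vermis_06
115	vermis_07
116	vermis_08
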