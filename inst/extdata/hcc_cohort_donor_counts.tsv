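donor	gender	virus	age	germline	private_germline	validated_tumor_specific
12	M	HCV	65	2082	202	3
15	M	HBV	53	1845	216	1
21	M	HCV	51	2019	271	0
29	M	HCV	52	1602	44	0
32	M	HBV	73	1681	100	0
33	F	HCV	57	1982	234	2
35	F	HCV	78	1786	96	0
42	F	HCV	67	1594	43	0
47	M	HBV	61	1581	77	2
48	M	HBV	35	1744	212	0
49	M	HCV	68	1644	58	0
60	M	HCV	48	1570	33	0
62	M	HBV	33	1750	153	0
70	M	HCV	55	1673	82	0
86	F	HBV	56	1701	50	0
89	M	HBV	60	1739	163	4
95	M	HBV	54	1773	88	0
106	M	HBV	60	2141	48	0
116	M	HBV	62	1532	71	0
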