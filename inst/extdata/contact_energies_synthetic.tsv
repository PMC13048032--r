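aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-0.388	-0.4533	0.1067	0.1067	-0.4813	-0.1827	0.0787	-0.64	0.144	-0.5747	-0.3973	0.1067	-0.0707	0.1067	0.2	-0.1453	-0.1547	-0.612	-0.136	-0.0987
C	-0.4533	-0.5259	0.0963	0.0963	-0.557	-0.2252	0.0652	-0.7333	0.1378	-0.6607	-0.4637	0.0963	-0.1007	0.0963	0.2	-0.1837	-0.1941	-0.7022	-0.1733	-0.1319
D	0.1067	0.0963	0.1852	0.1852	0.0919	0.1393	0.1807	0.0667	0.1911	0.077	0.1052	0.1852	0.157	0.1852	0.2	0.1452	0.1437	0.0711	0.1467	0.1526
E	0.1067	0.0963	0.1852	0.1852	0.0919	0.1393	0.1807	0.0667	0.1911	0.077	0.1052	0.1852	0.157	0.1852	0.2	0.1452	0.1437	0.0711	0.1467	0.1526
F	-0.4813	-0.557	0.0919	0.0919	-0.5895	-0.2434	0.0594	-0.7733	0.1351	-0.6976	-0.4921	0.0919	-0.1136	0.0919	0.2	-0.2001	-0.211	-0.7409	-0.1893	-0.1461
G	-0.1827	-0.2252	0.1393	0.1393	-0.2434	-0.049	0.121	-0.3467	0.1636	-0.3041	-0.1887	0.1393	0.0239	0.1393	0.2	-0.0247	-0.0308	-0.3284	-0.0187	0.0056
H	0.0787	0.0652	0.1807	0.1807	0.0594	0.121	0.175	0.0267	0.1884	0.0401	0.0767	0.1807	0.1441	0.1807	0.2	0.1287	0.1268	0.0324	0.1307	0.1384
I	-0.64	-0.7333	0.0667	0.0667	-0.7733	-0.3467	0.0267	-1	0.12	-0.9067	-0.6533	0.0667	-0.1867	0.0667	0.2	-0.2933	-0.3067	-0.96	-0.28	-0.2267
K	0.144	0.1378	0.1911	0.1911	0.1351	0.1636	0.1884	0.12	0.1947	0.1262	0.1431	0.1911	0.1742	0.1911	0.2	0.1671	0.1662	0.1227	0.168	0.1716
L	-0.5747	-0.6607	0.077	0.077	-0.6976	-0.3041	0.0401	-0.9067	0.1262	-0.8206	-0.587	0.077	-0.1566	0.077	0.2	-0.255	-0.2673	-0.8698	-0.2427	-0.1935
M	-0.3973	-0.4637	0.1052	0.1052	-0.4921	-0.1887	0.0767	-0.6533	0.1431	-0.587	-0.4068	0.1052	-0.075	0.1052	0.2	-0.1508	-0.1603	-0.6249	-0.1413	-0.1034
N	0.1067	0.0963	0.1852	0.1852	0.0919	0.1393	0.1807	0.0667	0.1911	0.077	0.1052	0.1852	0.157	0.1852	0.2	0.1452	0.1437	0.0711	0.1467	0.1526
P	-0.0707	-0.1007	0.157	0.157	-0.1136	0.0239	0.1441	-0.1867	0.1742	-0.1566	-0.075	0.157	0.0754	0.157	0.2	0.041	0.0367	-0.1738	0.0453	0.0625
Q	0.1067	0.0963	0.1852	0.1852	0.0919	0.1393	0.1807	0.0667	0.1911	0.077	0.1052	0.1852	0.157	0.1852	0.2	0.1452	0.1437	0.0711	0.1467	0.1526
R	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2	0.2
S	-0.1453	-0.1837	0.1452	0.1452	-0.2001	-0.0247	0.1287	-0.2933	0.1671	-0.255	-0.1508	0.1452	0.041	0.1452	0.2	-0.0028	-0.0083	-0.2769	0.0027	0.0246
T	-0.1547	-0.1941	0.1437	0.1437	-0.211	-0.0308	0.1268	-0.3067	0.1662	-0.2673	-0.1603	0.1437	0.0367	0.1437	0.2	-0.0083	-0.0139	-0.2898	-0.0027	0.0199
V	-0.612	-0.7022	0.0711	0.0711	-0.7409	-0.3284	0.0324	-0.96	0.1227	-0.8698	-0.6249	0.0711	-0.1738	0.0711	0.2	-0.2769	-0.2898	-0.9213	-0.264	-0.2124
W	-0.136	-0.1733	0.1467	0.1467	-0.1893	-0.0187	0.1307	-0.28	0.168	-0.2427	-0.1413	0.1467	0.0453	0.1467	0.2	0.0027	-0.0027	-0.264	0.008	0.0293
Y	-0.0987	-0.1319	0.1526	0.1526	-0.1461	0.0056	0.1384	-0.2267	0.1716	-0.1935	-0.1034	0.1526	0.0625	0.1526	0.2	0.0246	0.0199	-0.2124	0.0293	0.0483
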