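aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	3.881	3.9399	4.0405	4.0845	4.1637	3.8136	4.1254	4.0405	4.0845	4.0405	4.0405	4.0405	3.9926	4.0845	4.1637	3.9399	3.9926	3.9926	4.2661	4.1997
C	3.9399	3.9988	4.0994	4.1435	4.2226	3.8725	4.1844	4.0994	4.1435	4.0994	4.0994	4.0994	4.0515	4.1435	4.2226	3.9988	4.0515	4.0515	4.325	4.2586
D	4.0405	4.0994	4.2	4.244	4.3232	3.9731	4.2849	4.2	4.244	4.2	4.2	4.2	4.1521	4.244	4.3232	4.0994	4.1521	4.1521	4.4256	4.3592
E	4.0845	4.1435	4.244	4.2881	4.3672	4.0171	4.329	4.244	4.2881	4.244	4.244	4.244	4.1962	4.2881	4.3672	4.1435	4.1962	4.1962	4.4696	4.4032
F	4.1637	4.2226	4.3232	4.3672	4.4464	4.0963	4.4081	4.3232	4.3672	4.3232	4.3232	4.3232	4.2753	4.3672	4.4464	4.2226	4.2753	4.2753	4.5488	4.4824
G	3.8136	3.8725	3.9731	4.0171	4.0963	3.7461	4.058	3.9731	4.0171	3.9731	3.9731	3.9731	3.9252	4.0171	4.0963	3.8725	3.9252	3.9252	4.1986	4.1323
H	4.1254	4.1844	4.2849	4.329	4.4081	4.058	4.3699	4.2849	4.329	4.2849	4.2849	4.2849	4.2371	4.329	4.4081	4.1844	4.2371	4.2371	4.5105	4.4441
I	4.0405	4.0994	4.2	4.244	4.3232	3.9731	4.2849	4.2	4.244	4.2	4.2	4.2	4.1521	4.244	4.3232	4.0994	4.1521	4.1521	4.4256	4.3592
K	4.0845	4.1435	4.244	4.2881	4.3672	4.0171	4.329	4.244	4.2881	4.244	4.244	4.244	4.1962	4.2881	4.3672	4.1435	4.1962	4.1962	4.4696	4.4032
L	4.0405	4.0994	4.2	4.244	4.3232	3.9731	4.2849	4.2	4.244	4.2	4.2	4.2	4.1521	4.244	4.3232	4.0994	4.1521	4.1521	4.4256	4.3592
M	4.0405	4.0994	4.2	4.244	4.3232	3.9731	4.2849	4.2	4.244	4.2	4.2	4.2	4.1521	4.244	4.3232	4.0994	4.1521	4.1521	4.4256	4.3592
N	4.0405	4.0994	4.2	4.244	4.3232	3.9731	4.2849	4.2	4.244	4.2	4.2	4.2	4.1521	4.244	4.3232	4.0994	4.1521	4.1521	4.4256	4.3592
P	3.9926	4.0515	4.1521	4.1962	4.2753	3.9252	4.2371	4.1521	4.1962	4.1521	4.1521	4.1521	4.1042	4.1962	4.2753	4.0515	4.1042	4.1042	4.3777	4.3113
Q	4.0845	4.1435	4.244	4.2881	4.3672	4.0171	4.329	4.244	4.2881	4.244	4.244	4.244	4.1962	4.2881	4.3672	4.1435	4.1962	4.1962	4.4696	4.4032
R	4.1637	4.2226	4.3232	4.3672	4.4464	4.0963	4.4081	4.3232	4.3672	4.3232	4.3232	4.3232	4.2753	4.3672	4.4464	4.2226	4.2753	4.2753	4.5488	4.4824
S	3.9399	3.9988	4.0994	4.1435	4.2226	3.8725	4.1844	4.0994	4.1435	4.0994	4.0994	4.0994	4.0515	4.1435	4.2226	3.9988	4.0515	4.0515	4.325	4.2586
T	3.9926	4.0515	4.1521	4.1962	4.2753	3.9252	4.2371	4.1521	4.1962	4.1521	4.1521	4.1521	4.1042	4.1962	4.2753	4.0515	4.1042	4.1042	4.3777	4.3113
V	3.9926	4.0515	4.1521	4.1962	4.2753	3.9252	4.2371	4.1521	4.1962	4.1521	4.1521	4.1521	4.1042	4.1962	4.2753	4.0515	4.1042	4.1042	4.3777	4.3113
W	4.2661	4.325	4.4256	4.4696	4.5488	4.1986	4.5105	4.4256	4.4696	4.4256	4.4256	4.4256	4.3777	4.4696	4.5488	4.325	4.3777	4.3777	4.6512	4.5848
Y	4.1997	4.2586	4.3592	4.4032	4.4824	4.1323	4.4441	4.3592	4.4032	4.3592	4.3592	4.3592	4.3113	4.4032	4.4824	4.2586	4.3113	4.3113	4.5848	4.5184
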