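aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	13	14	11	14	10	16	10	11	10	11	14	13	11	11	6	9	8	21	15
C	13	0	21	22	19	21	23	15	20	15	16	21	22	20	20	15	16	15	24	20
D	14	21	0	7	18	14	16	16	13	18	17	10	15	11	15	10	13	16	25	19
E	11	22	7	0	17	15	13	15	8	15	14	11	14	6	10	9	12	13	22	16
F	14	19	18	17	0	18	16	10	17	10	11	18	21	17	17	14	15	12	15	7
G	10	21	14	15	18	0	18	18	15	18	17	12	17	15	15	10	15	16	21	19
H	16	23	16	13	16	18	0	18	15	18	17	12	19	13	13	14	17	18	23	11
I	10	15	16	15	10	18	18	0	15	4	7	16	17	15	15	12	11	2	21	13
K	11	20	13	8	17	15	15	15	0	13	12	11	14	8	6	9	12	13	22	16
L	10	15	18	15	10	18	18	4	13	0	5	16	17	13	13	12	11	6	19	13
M	11	16	17	14	11	17	17	7	12	5	0	15	16	10	12	11	12	7	18	14
N	14	21	10	11	18	12	12	16	11	16	15	0	17	11	11	8	11	16	25	17
P	13	22	15	14	21	17	19	17	14	17	16	17	0	14	16	13	14	15	26	20
Q	11	20	11	6	17	15	13	15	8	13	10	11	14	0	8	9	12	13	20	14
R	11	20	15	10	17	15	13	15	6	13	12	11	16	8	0	11	12	15	22	16
S	6	15	10	9	14	10	14	12	9	12	11	8	13	9	11	0	7	12	21	15
T	9	16	13	12	15	15	17	11	12	11	12	11	14	12	12	7	0	9	20	16
V	8	15	16	13	12	16	18	2	13	6	7	16	15	13	15	12	9	0	21	13
W	21	24	25	22	15	21	23	21	22	19	18	25	26	20	22	21	20	21	0	14
Y	15	20	19	16	7	19	11	13	16	13	14	17	20	14	16	15	16	13	14	0
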