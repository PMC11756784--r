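# SYNTHETIC stand-in for a low-range (max 4) amino-acid similarity table.
# Constructed as zero-floored BLOSUM62 clipped at 4; it is NOT a transcription
# of any published WAC table. Symmetric, all entries in 0..4, maximum 4.
aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0
C	0	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
D	0	0	4	2	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0
E	0	0	2	4	0	0	0	0	1	0	0	0	0	2	0	0	0	0	0	0
F	0	0	0	0	4	0	0	0	0	0	0	0	0	0	0	0	0	0	1	3
G	0	0	0	0	0	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0
H	0	0	0	0	0	0	4	0	0	0	0	1	0	0	0	0	0	0	0	2
I	0	0	0	0	0	0	0	4	0	2	1	0	0	0	0	0	0	3	0	0
K	0	0	0	1	0	0	0	0	4	0	0	0	0	1	2	0	0	0	0	0
L	0	0	0	0	0	0	0	2	0	4	2	0	0	0	0	0	0	1	0	0
M	0	0	0	0	0	0	0	1	0	2	4	0	0	0	0	0	0	1	0	0
N	0	0	1	0	0	0	1	0	0	0	0	4	0	0	0	1	0	0	0	0
P	0	0	0	0	0	0	0	0	0	0	0	0	4	0	0	0	0	0	0	0
Q	0	0	0	2	0	0	0	0	1	0	0	0	0	4	1	0	0	0	0	0
R	0	0	0	0	0	0	0	0	2	0	0	0	0	1	4	0	0	0	0	0
S	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	4	1	0	0	0
T	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	4	0	0	0
V	0	0	0	0	0	0	0	3	0	1	1	0	0	0	0	0	0	4	0	0
W	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	4	2
Y	0	0	0	0	3	0	2	0	0	0	0	0	0	0	0	0	0	0	2	4
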