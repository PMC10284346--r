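AA	KYTJ820101	GRAR740102	EISD860101
A	1.8	8.1	0.67
R	-4.5	10.5	-2.1
N	-3.5	11.6	-0.6
D	-3.5	13.0	-1.2
C	2.5	5.5	0.38
Q	-3.5	10.5	-0.22
E	-3.5	12.3	-0.76
G	-0.4	9.0	0.0
H	-3.2	10.4	0.64
I	4.5	5.2	1.9
L	3.8	4.9	1.9
K	-3.9	11.3	-0.57
M	1.9	5.7	2.4
F	2.8	5.2	2.3
P	-1.6	8.0	1.2
S	-0.8	9.2	0.01
T	-0.7	8.6	0.52
W	-0.9	5.4	2.6
Y	-1.3	6.2	1.6
V	4.2	5.9	1.5
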