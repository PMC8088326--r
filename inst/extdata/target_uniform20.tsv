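# Uniform target over the 20 canonical residues
A	1
C	1
D	1
E	1
F	1
G	1
H	1
I	1
K	1
L	1
M	1
N	1
P	1
Q	1
R	1
S	1
T	1
V	1
W	1
Y	1
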