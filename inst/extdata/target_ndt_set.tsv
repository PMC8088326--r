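# Uniform target over the 12 residues of the NDT codon set,
# a common reduced alphabet for protein engineering
R	1
N	1
D	1
C	1
G	1
H	1
I	1
L	1
F	1
S	1
Y	1
V	1
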