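# Uniform target over a reduced "early" amino-acid alphabet
A	1
S	1
D	1
G	1
L	1
E	1
T	1
I	1
P	1
V	1
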