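residue	symbol
A	a
G	a
N	a
P	a
S	a
T	a
C	b
H	b
W	b
Y	b
D	c
E	c
K	c
Q	c
R	c
F	d
I	d
L	d
M	d
V	d
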