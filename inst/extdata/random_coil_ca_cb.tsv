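# provenance: Wishart/Sykes random-coil 13C shifts (DSS-referenced), standard literature values
res_type	nucleus	shift_ppm
A	CA	52.5
A	CB	19.1
C	CA	58.2
C	CB	28.0
D	CA	54.2
D	CB	41.1
E	CA	56.6
E	CB	29.9
F	CA	58.0
F	CB	39.0
G	CA	45.1
H	CA	55.0
H	CB	29.0
I	CA	61.3
I	CB	38.0
K	CA	56.2
K	CB	33.1
L	CA	55.1
L	CB	42.4
M	CA	55.4
M	CB	32.9
N	CA	53.1
N	CB	38.9
P	CA	63.3
P	CB	31.7
Q	CA	55.7
Q	CB	29.4
R	CA	56.0
R	CB	30.9
S	CA	58.3
S	CB	63.8
T	CA	61.8
T	CB	69.8
V	CA	62.2
V	CB	32.9
W	CA	57.5
W	CB	29.6
Y	CA	58.1
Y	CB	38.8
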