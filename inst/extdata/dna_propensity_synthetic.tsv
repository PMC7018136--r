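# Synthetic amino-acid protein-DNA interface propensity scale.
# Stand-in reproducing the range (0-2.534, arginine maximal) and the
# qualitative ordering of published protein-DNA interface propensities:
# positively charged and polar residues high, hydrophobic and acidic
# residues low. Replace with a published scale via read_propensities(path)
# for production use.
aa	raw
R	2.534
K	1.890
N	1.380
S	1.300
T	1.220
G	1.210
H	1.090
Q	1.050
Y	0.880
W	0.600
A	0.510
M	0.420
P	0.400
C	0.360
F	0.340
E	0.330
D	0.320
V	0.310
I	0.270
L	0.220
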