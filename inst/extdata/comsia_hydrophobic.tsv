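# CoMSIA hydrophobic atomic weights, version 1.0
# Coarse atom-class hydrophobicity (dimensionless): positive = hydrophobic,
# negative = hydrophilic. H_polar = hydrogen bound to O/N/S.
atom_class	weight
C	0.5
H_on_C	0.2
H_polar	-0.25
N	-1.0
O	-1.0
S	0.4
P	0.0
F	0.3
Cl	0.3
Br	0.3
I	0.3
default	0.0
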