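# van der Waals parameters, version 1.0
# Element-keyed radii (Angstrom) and well depths (kcal/mol), patterned on
# the Tripos force field so probe-interaction energies are reproducible
# bit-for-bit across machines. Editable; bump the version when changed.
element	vdw_r	vdw_eps
C	1.70	0.107
H	1.50	0.042
N	1.55	0.095
O	1.52	0.116
S	1.80	0.314
P	1.80	0.314
F	1.47	0.109
Cl	1.75	0.314
Br	1.85	0.434
I	1.98	0.623
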