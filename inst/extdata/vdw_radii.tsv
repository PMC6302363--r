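# Element-keyed van der Waals radii (Angstrom), NACCESS-style values.
# Edit or replace via the `radii` argument of the SASA functions.
element	radius
C	1.87
N	1.65
O	1.40
P	1.90
S	1.85
H	1.00
D	1.00
SE	1.90
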