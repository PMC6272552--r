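# Generic united-charge all-atom alkane parameters (OPLS-like LJ).
# Units: kcal/mol, Angstrom, degrees; E = k/2 (x-x0)^2 for harmonic terms.
NONBONDED
# type  charge  eps     rmin
CT3     -0.18   0.066   3.928
CT2     -0.12   0.066   3.928
HC       0.06   0.030   2.806
BONDS
CT3 CT3   536.0  1.529
CT3 CT2   536.0  1.529
CT2 CT2   536.0  1.529
CT3 HC    680.0  1.090
CT2 HC    680.0  1.090
ANGLES
HC  CT3 HC    66.0  107.8
HC  CT2 HC    66.0  107.8
CT3 CT2 HC    75.0  110.7
CT2 CT2 HC    75.0  110.7
CT2 CT3 HC    75.0  110.7
CT3 CT3 HC    75.0  110.7
CT3 CT2 CT2  116.7  112.7
CT2 CT2 CT2  116.7  112.7
CT3 CT2 CT3  116.7  112.7
DIHEDRALS
X CT2 CT2 X   0.30  3  0.0
X CT3 CT2 X   0.30  3  0.0
X CT3 CT3 X   0.30  3  0.0
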