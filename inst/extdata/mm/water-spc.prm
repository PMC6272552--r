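# Rigid-geometry 3-site water (SPC charges); stiff harmonic bonds stand in
# for constraints. Units: kcal/mol, Angstrom, degrees; E = k/2 (x-x0)^2.
NONBONDED
# type  charge  eps      rmin
OW      -0.82   0.1553   3.5532
HW       0.41   0.0      0.4
BONDS
OW HW   900.0   0.9572
ANGLES
HW OW HW  110.0  104.52
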