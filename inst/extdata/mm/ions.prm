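# Monatomic ion nonbonded parameters (generic CHARMM-like values).
# Units: kcal/mol, Angstrom.
NONBONDED
# type  charge  eps      rmin
NA       1.0    0.0469   2.8215
K        1.0    0.0870   3.5275
CL      -1.0    0.1500   4.5400
BR      -1.0    0.1600   4.9000
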