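# Per-element atom parameters used by the field engine.
#   vdw_radius   : van der Waals radius, Angstrom (Bondi compilation)
#   lj_epsilon   : Lennard-Jones well depth, kcal/mol (Tripos-style values)
#   hydrophobicity: coarse element-level atomic lipophilicity contribution,
#                   dimensionless; sign convention: positive = lipophilic.
#                   A deliberately simple surrogate for fragment-based atomic
#                   logP contributions; swappable via assign_atom_parameters().
element,vdw_radius,lj_epsilon,hydrophobicity
H,1.20,0.042,0.10
C,1.70,0.107,0.34
N,1.55,0.095,-0.60
O,1.52,0.116,-0.45
F,1.47,0.109,0.20
P,1.80,0.314,-0.20
S,1.80,0.314,0.30
Cl,1.75,0.314,0.50
Br,1.85,0.434,0.60
I,1.98,0.623,0.70
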