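# Ethanol intramolecular force-field parameters.
# Units: kcal/mol, Angstrom, degrees.
#
# Bond rows carry the published MP2-force-matched stretch parameters
# (k_bond in kcal/mol/A^2, r_e in A, D_e in kcal/mol):
#   bond typeA typeB k_bond r_e D_e
bond CT CT 551.9110  1.5204  82.69
bond OH HO 1056.6764 0.9609 110.66
bond CT OH 577.2346  1.4396  85.56
bond CT HC 742.5561  1.0937  98.71
#
# The angle and dihedral constants below are SYNTHETIC stand-ins with
# typical magnitudes for an alcohol: the source force field's bending and
# torsion values are not published alongside the stretches.  Angles:
#   angle typeA typeB typeC k_angle theta_e_deg   (typeB central)
angle HC CT HC  70.0 107.8
angle HC CT CT  75.0 110.7
angle HC CT OH  80.0 109.5
angle CT CT OH 120.0 108.4
angle CT OH HO 110.0 108.5
#
# Dihedrals: k*(1 + cos(n*phi - delta)); 3-fold rotors, delta = 0:
#   dihedral typeA typeB typeC typeD k n delta_deg
dihedral HC CT CT HC 0.30 3 0
dihedral HC CT CT OH 0.30 3 0
dihedral HC CT OH HO 0.35 3 0
dihedral CT CT OH HO 0.40 3 0
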