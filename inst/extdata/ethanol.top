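# Ethanol topology.  Atom order matches the contiguous "321111"
# permutational symmetry: 3 methyl H, 2 methylene H, methyl C,
# methylene C, O, hydroxyl H.
atom 1 H HC
atom 2 H HC
atom 3 H HC
atom 4 H HC
atom 5 H HC
atom 6 C CT
atom 7 C CT
atom 8 O OH
atom 9 H HO
# bonds (8): C-C, C-O, O-H, 5 x C-H
bond 6 7
bond 7 8
bond 8 9
bond 6 1
bond 6 2
bond 6 3
bond 7 4
bond 7 5
# angles (13), central atom second
angle 1 6 2
angle 1 6 3
angle 2 6 3
angle 1 6 7
angle 2 6 7
angle 3 6 7
angle 4 7 5
angle 4 7 6
angle 5 7 6
angle 4 7 8
angle 5 7 8
angle 6 7 8
angle 7 8 9
# dihedrals (12): 9 about the C-C bond, 3 about the C-O bond
dihedral 1 6 7 4
dihedral 1 6 7 5
dihedral 1 6 7 8
dihedral 2 6 7 4
dihedral 2 6 7 5
dihedral 2 6 7 8
dihedral 3 6 7 4
dihedral 3 6 7 5
dihedral 3 6 7 8
dihedral 4 7 8 9
dihedral 5 7 8 9
dihedral 6 7 8 9
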