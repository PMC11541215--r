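# Protein-glycan linkage geometry, one row per supported glycosylation type.
# Atom naming follows the a-e convention for the two linkage torsions:
#   phi = a-b-c-d, psi = b-c-d-e, with a/b on the glycan (ring oxygen and
#   anomeric carbon) and c/d/e on the protein sidechain. Column c may carry
#   a comma-separated preference list resolved against the residue (e.g.
#   OG for Ser, OG1 for Thr).
# Torsion ranges are degrees within (-180, 180]. They default to
# conventional glycosidic-linkage statistics (phi confined to the
# exo-anomeric region for N- and O-linkages, psi left free) and are meant
# to be tightened or replaced by users with linkage-specific data.
# bond_length is the b-c bond (Angstrom); bond_angle is the b-c-d angle
# (degrees) used when placing the anomeric carbon.
glyco_type,residues,a,b,c,d,e,phi_min,phi_max,psi_min,psi_max,bond_length,bond_angle
N-GlcNAc,ASN,O5,C1,ND2,CG,CB,-150,-50,-180,180,1.45,124
O-GalNAc,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
O-GlcNAc,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
O-Fuc,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
O-Man,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
O-Glc,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
O-Xyl,SER/THR,O5,C1,"OG,OG1",CB,CA,-180,180,-180,180,1.43,117
C-Man,TRP,O5,C1,CD1,CG,CB,-180,180,-180,180,1.50,126
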