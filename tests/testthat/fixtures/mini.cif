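data_mini
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 C CA . GLY A 1 1 ? 0.000 0.000 0.000 1.00 85.00 ? 1 GLY A CA 1
ATOM 2 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 90.00 ? 2 GLY A CA 1
ATOM 3 C CA . GLY A 1 3 ? 7.600 1.000 0.000 1.00 95.00 ? 3 GLY A CA 1
ATOM 4 C CA . GLY B 1 1 ? 0.000 5.000 0.000 1.00 80.00 ? 1 GLY B CA 1
ATOM 5 C CA . GLY B 1 2 ? 3.800 5.000 0.000 1.00 80.00 ? 2 GLY B CA 1
#
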