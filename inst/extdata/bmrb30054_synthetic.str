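# SYNTHETIC stand-in shift file (NMR-STAR 3.x shift-loop subset).
# Hand-written fixture holding the published backbone 31P chemical shifts
# of the [Sp,Sp]-phosphorothioate decamer duplex at its modified sites
# (G3, G17); it is NOT the deposited BMRB entry.
data_synthetic_sp_duplex

save_assigned_chemical_shifts
   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts

   loop_
      _Atom_chem_shift.ID
      _Atom_chem_shift.Comp_index_ID
      _Atom_chem_shift.Comp_ID
      _Atom_chem_shift.Atom_ID
      _Atom_chem_shift.Atom_type
      _Atom_chem_shift.Val

      1  3 SSG P P 0.47
      2 17 SSG P P 0.54
   stop_
save_
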