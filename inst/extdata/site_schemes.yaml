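# Binding-site boundary schemes for the selectivity filter.
#
# Each scheme lists the six oxygen rings that stack along the pore axis, from
# the extracellular (top) to the intracellular (bottom) side. Consecutive ring
# pairs delineate the five K+ binding sites S0 (extracellular) to S4
# (intracellular); each site is therefore bounded by 8 oxygen atoms
# (4 subunits x 2 rings). The four inner rings are the boundaries between
# successive sites: for hERG, F627 O separates S0/S1, G626 O S1/S2, V625 O
# S2/S3 and S624 O S3/S4; the S4 site is capped below by the Ser624 side-chain
# hydroxyl (Thr75 OG1 in KcsA).
herg:
  sf_range: [623, 629]
  rings:
    - {resno: 628, elety: O}
    - {resno: 627, elety: O}
    - {resno: 626, elety: O}
    - {resno: 625, elety: O}
    - {resno: 624, elety: O}
    - {resno: 624, elety: OG}
kcsa:
  sf_range: [74, 80]
  rings:
    - {resno: 79, elety: O}
    - {resno: 78, elety: O}
    - {resno: 77, elety: O}
    - {resno: 76, elety: O}
    - {resno: 75, elety: O}
    - {resno: 75, elety: OG1}
# Residue correspondence used for backbone RMSD between the two channels
# (hERG Thr623-Asn629 onto KcsA Thr74-Asp80).
residue_maps:
  herg_to_kcsa:
    query: [623, 624, 625, 626, 627, 628, 629]
    reference: [74, 75, 76, 77, 78, 79, 80]
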