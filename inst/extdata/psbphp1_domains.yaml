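# Default domain windows for photostate comparisons of the P. syringae
# BphP1 photoreceptor, in deposited (author) residue numbering. The domain
# boundaries are approximate windows chosen from the domain architecture of
# the 745-residue polypeptide; users comparing other phytochromes, or
# wanting exact deposited boundaries, should override this file.
default_chain: A
domains:
  PAS: [30, 130]
  GAF: [131, 320]
  PHY: [321, 500]
  S_helix: [495, 528]
  DHp: [529, 590]
# Phosphoacceptor histidine of the kinase bidomain.
phosphoacceptor_resno: 530
# Hairpin-proximity distance pair (Calpha-Calpha), shortens on
# photoactivation.
distance_pair:
  a: {chain: A, resno: 177, elety: CA}
  b: {chain: A, resno: 483, elety: CA}
# Biliverdin D ring: the five-membered pyrrole ring bearing the 18-vinyl
# substituent. Atom names follow the BLA chemical-component dictionary
# entry so dialect-specific names stay out of code.
dring:
  ligand: BLA
  atoms: [ND, C16, C17, C18, C19]
# Synthetic fixtures generated by makeRotatedPair() use this ring instead.
dring_synthetic:
  ligand: RNG
  atoms: [C1, C2, C3, C4, C5]
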