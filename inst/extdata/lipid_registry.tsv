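# memshape lipid-name registry: residue names mapped to entity_kind=lipid.
# chain: "long" = bilayer-forming long-chain lipid, "short" = rim-stabilizing
# short-chain lipid. Extend by passing your own table to read_trajectory().
species	chain
DMPC	long
DHPC	short
POPC	long
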