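gene	eif2a_target	description
TOS1	TRUE	Covalently-bound cell wall protein of unknown function
LRE1	FALSE	Protein involved in control of cell wall structure and stress response
SCW4	TRUE	Cell wall protein with similarity to glucanases
DSE2	TRUE	Daughter cell-specific secreted protein, similarity to glucanases
SIM1	TRUE	Protein of the SUN family (Sim1p, Uth1p, Nca3p, Sun4p)
HSL1	FALSE	Septin-binding kinase that localizes to the bud neck septin ring
UTH1	TRUE	Mitochondrial inner membrane protein implicated in cell wall biogenesis
MMR1	FALSE	Mitochondrial Myo2p Receptor-related
CTS1	TRUE	Endochitinase
SUN4	TRUE	Cell wall protein related to glucanases localized in birth scars
SRL1	TRUE	Mannoprotein that exhibits a tight association with the cell wall
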