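# Structural-alert catalogue: reactive/unstable and non-druglike motifs
# removed from the acid library before diversity selection.
# kind = smarts: OpenBabel SMARTS query; element: comma-separated element
# symbols; chain: built-in long-chain fatty-acid rule (pattern = minimum
# chain length in carbons).
name	category	kind	pattern
aminonitrile	reactive	smarts	[NX3;!$(N=*)][CX4][CX2]#[NX1]
thionitrile	reactive	smarts	[SX2][CX2]#[NX1]
epoxide	reactive	smarts	[#6r3]1[#6r3][OX2r3]1
aziridine	reactive	smarts	[#6r3]1[#6r3][NX3r3]1
disulfide	reactive	smarts	[SX2][SX2]
nitrogen_oxide	reactive	smarts	[$([#7+][#8X1-]),$([#7]=[OX1])]
azo	reactive	smarts	[#6][NX2]=[NX2][#6]
beta_lactam	reactive	smarts	O=C1CCN1
gem_dicarboxylic	non_druglike	smarts	[CX4](C(=O)[OX2H1])C(=O)[OX2H1]
quaternary_ammonium	non_druglike	smarts	[NX4+]([#6])([#6])([#6])[#6]
long_chain_fatty_acid	non_druglike	chain	8
boron_selenium_silicon	non_druglike	element	B,Se,Si
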