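# Starter salt dictionary: SMILES<TAB>name, one entry per line.
# Matching is insensitive to charge state, depicted stereochemistry and
# cis/trans isomerism, so only one representative per skeleton may be
# listed (e.g. maleate also matches fumarate; acetate also matches acetic
# acid; chloride also matches HCl). Derived from the USAN pharmacological
# salt classes; extend freely.
Cl	hydrochloride
Br	hydrobromide
I	hydroiodide
F	hydrofluoride
OS(=O)(=O)O	sulfate
OP(=O)(O)O	phosphate
O[N+](=O)[O-]	nitrate
OC(=O)O	carbonate
CC(=O)O	acetate
OC(F)(F)C(F)(F)F	pentafluoropropionate
FC(F)(F)C(=O)O	trifluoroacetate
OC(=O)C=CC(=O)O	maleate
OC(C(O)C(=O)O)C(=O)O	tartrate
OC(CC(=O)O)C(=O)O	malate
OC(=O)CC(O)(CC(=O)O)C(=O)O	citrate
OC(=O)CCC(=O)O	succinate
OC(=O)C(=O)O	oxalate
OC=O	formate
CC(O)C(=O)O	lactate
OCC(O)C(O)C(O)C(O)C(=O)O	gluconate
CCCCCCCCCCCCCCCCCC(=O)O	stearate
CS(=O)(=O)O	mesylate
CCS(=O)(=O)O	esylate
OS(=O)(=O)CCS(=O)(=O)O	edisylate
c1ccccc1S(=O)(=O)O	besylate
Cc1ccc(cc1)S(=O)(=O)O	tosylate
OS(=O)(=O)c1ccc2ccccc2c1	napsylate
CC1(C)C2CCC1(CS(=O)(=O)O)C(=O)C2	camsylate
OC(=O)c1cc2ccccc2c(Cc2c(O)c(cc3ccccc23)C(=O)O)c1O	pamoate
[Na+]	sodium
[K+]	potassium
[Li+]	lithium
[Ca+2]	calcium
[Mg+2]	magnesium
[Zn+2]	zinc
[Al+3]	aluminium
N	ammonium
CNC[C@@H](O)[C@@H](O)[C@H](O)[C@H](O)CO	meglumine
OCC(N)(CO)CO	tromethamine
OCCNCCO	diethanolamine
NCCN	ethylenediamine
C1CNCCN1	piperazine
C[N+](C)(C)CCO	choline
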