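# Crystallization solvents removable by the parent stage.
# SMILES<TAB>name.
O	water
CO	methanol
CCO	ethanol
CC(C)O	2-propanol
CC(C)=O	acetone
CC#N	acetonitrile
CS(C)=O	dimethyl sulfoxide
CCOC(C)=O	ethyl acetate
CCOCC	diethyl ether
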