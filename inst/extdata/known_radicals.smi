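# Known stable radicals accepted without a checker flag.
# SMILES<TAB>name; aminoxyl-type N-O monoradicals are additionally
# recognised structurally and need not be listed.
[N]=O	nitric oxide
[O]N=O	nitrogen dioxide
CC1(C)CCCC(C)(C)N1[O]	TEMPO
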