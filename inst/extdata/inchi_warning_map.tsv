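# Mapping of InChI engine warnings to checker issues.
# `pattern` is matched as a fixed substring of the verbatim warning;
# warnings matching no pattern are reported as "InChI: <warning>" at score 2
# (the "Other InChI Warnings" class).
pattern	score	label
Unknown element	7	InChI: Unknown element(s)
Accepted unusual valence	6	InChI: Accepted unusual valence(s)
Empty structure	6	InChI: Empty structure
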