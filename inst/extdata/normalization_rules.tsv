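# Ordered structure-normalization rule set applied by the standardizer.
# Columns: name, pattern (SMARTS, documentation of what each rule matches),
# transform (description). Rules run in this order, iterated to a fixpoint.
# Removing a line disables the rule; the graph edits themselves are
# implemented in the package.
name	pattern	transform
nitro	[N;X3:1](=[O:2])=[O:3]	hypervalent nitro to charge-separated [N+](=O)[O-]
alkali_metal	[Li,Na,K,Rb,Cs;+0]-[O,N;+0]	covalent alkali metal-O/N bond to ionic pair
amide_tautomer	[N;+0:1]=[C:2]-[OX2H1;+0:3]	imidic acid N=C-OH to amide N-C(=O)
sulfoxide	[S;X3;+0:1](=[O;X1;+0:2])	sulfoxide S=O to charge-separated [S+]-[O-]
diazonium	[*:1]-[N;+0:2]=[N;X1;+0:3]	terminal diazo R-N=N to diazonium R-[N+]#N
quaternary_N	[N;X4;v4;+0]	quaternary nitrogen gains its positive charge
trivalent_O	[O;X3;v3;+0]	trivalent oxygen gains its positive charge
trivalent_S	[S;X3;v3;+0;!$(S=*)]	trivalent sulfur (sulfonium) gains its positive charge
lone_halogen	[F,Cl,Br,I;X0;+0]	disconnected halogen atom gains its negative charge
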