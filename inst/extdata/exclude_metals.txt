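# Element symbols whose presence sets the standardizer exclude flag
# (organometallics and related species whose coordination bonds a V2000
# connection table cannot represent faithfully). One symbol per line.
Sc
Ti
V
Cr
Mn
Fe
Co
Ni
Cu
Ga
Y
Zr
Nb
Mo
Tc
Ru
Rh
Pd
Cd
In
Sn
La
Hf
Ta
W
Re
Os
Ir
Pt
Au
Hg
Tl
Pb
Bi
Po
Ac
Ce
Pr
Nd
Pm
Sm
Eu
Gd
Tb
Dy
Ho
Er
Tm
Yb
Lu
Th
Pa
U
Np
Pu
Am
Cm
Bk
Cf
Es
Fm
Md
No
Lr
Ge
Sb
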