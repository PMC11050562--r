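alert_name	smarts	source
primary_amine	[NX3;H2;!$([NX3][CX3]=[OX1]);!$([NX3][SX4])]	builtin
secondary_amine	[NX3;H1;!$([NX3][CX3]=[OX1]);!$([NX3][SX4])]([#6])[#6]	builtin
tertiary_amine	[NX3;H0;!$([NX3][CX3]=[OX1]);!$([NX3][SX4])]([#6])([#6])[#6]	builtin
aniline	[NX3][c]	builtin
alcohol	[OX2H1][CX4]	builtin
ether	[OX2H0;!$([OX2][CX3]=[OX1])]([#6])[#6]	builtin
aromatic_halide	[c][F,Cl,Br,I]	builtin
aliphatic_halide	[CX4][F,Cl,Br,I]	builtin
carboxylic_acid	[CX3](=[OX1])[OX2H1]	builtin
imide_NH	[NX3;H1]([CX3]=[OX1])[CX3]=[OX1]	builtin
primary_amide	[NX3;H2][CX3]=[OX1]	builtin
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]	builtin
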