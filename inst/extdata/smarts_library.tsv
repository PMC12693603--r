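name	smarts	priority
carboxylic_acid	[CX3](=O)[OX2H]	1
ester	[CX3](=O)[OX2][#6]	2
amide	[CX3](=O)[NX3]	3
acyl_halide	[CX3](=O)[F,Cl,Br]	4
carbamate	[NX3][CX3](=O)[OX2]	5
aldehyde	[CX3H1]=O	6
ketone	[#6][CX3](=O)[#6]	7
lactone_oxygen	[OX2r5][CX3]=O	8
thioester	[CX3](=O)[SX2]	9
nitrile	[NX1]#[CX2]	10
nitro	[NX3](=O)=O	11
phenol	[OX2H]c	12
enol	[OX2H][CX3]=[CX3]	13
primary_alcohol	[OX2H][CX4H2]	14
secondary_alcohol	[OX2H][CX4H1]	15
tertiary_alcohol	[OX2H][CX4H0]	16
alcohol	[OX2H][CX4]	17
thiol	[SX2H]	18
disulfide	[SX2][SX2]	19
thioether	[#6][SX2][#6]	20
aryl_ether	[OX2](c)[#6]	21
ether	[CX4][OX2][CX4]	22
peroxide	[OX2][OX2]	23
primary_amine	[NX3H2][#6]	24
secondary_amine	[#6][NX3H1][#6]	25
tertiary_amine	[#6][NX3H0]([#6])[#6]	26
aromatic_nitrogen	[nX2]	27
pyrrole_nitrogen	[nX3]	28
imine	[CX3]=[NX2]	29
phosphine	[PX3]	30
phosphate_like	[PX4]	31
alkoxide_sodium	[OX2][Na]	32
organosodium	[Na]	33
fluoro	[F][#6]	34
chloro	[Cl][#6]	35
bromo	[Br][#6]	36
alkyne	[CX2]#[CX2]	37
allene_carbon	[CX2](=*)=*	38
alkene	[CX3]=[CX3]	39
benzene_ring	c1ccccc1	40
furan_ring	o1cccc1	41
thiophene_ring	s1cccc1	42
aromatic_carbon	c	43
cyclopropane_carbon	[CX4r3]	44
cyclobutane_carbon	[CX4r4]	45
cyclopentane_carbon	[CX4r5]	46
cyclohexane_carbon	[CX4r6]	47
quaternary_carbon	[CX4H0]	48
methine	[CX4H1]	49
methylene	[CX4H2]	50
methyl	[CX4H3]	51
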