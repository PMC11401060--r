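residue	atom	classes
*	N	HydrogenDonor
*	CA	Neutral
*	C	Neutral
*	O	HydrogenAcceptor
*	OXT	HydrogenAcceptor
PRO	N	Neutral
ALA	CB	Hydrophobic
ARG	CB	Hydrophobic
ARG	CG	Hydrophobic
ARG	CD	Neutral
ARG	NE	HydrogenDonor;PositiveIonizable
ARG	CZ	Neutral
ARG	NH1	HydrogenDonor;PositiveIonizable
ARG	NH2	HydrogenDonor;PositiveIonizable
ASN	CB	Hydrophobic
ASN	CG	Neutral
ASN	OD1	HydrogenAcceptor
ASN	ND2	HydrogenDonor
ASP	CB	Hydrophobic
ASP	CG	Neutral
ASP	OD1	HydrogenAcceptor;NegativeIonizable
ASP	OD2	HydrogenAcceptor;NegativeIonizable
CYS	CB	Hydrophobic
CYS	SG	Sulfur
GLN	CB	Hydrophobic
GLN	CG	Hydrophobic
GLN	CD	Neutral
GLN	OE1	HydrogenAcceptor
GLN	NE2	HydrogenDonor
GLU	CB	Hydrophobic
GLU	CG	Hydrophobic
GLU	CD	Neutral
GLU	OE1	HydrogenAcceptor;NegativeIonizable
GLU	OE2	HydrogenAcceptor;NegativeIonizable
HIS	CB	Hydrophobic
HIS	CG	Aromatic
HIS	ND1	Aromatic;HydrogenDonor;HydrogenAcceptor;PositiveIonizable
HIS	CD2	Aromatic
HIS	CE1	Aromatic
HIS	NE2	Aromatic;HydrogenDonor;HydrogenAcceptor;PositiveIonizable
ILE	CB	Hydrophobic
ILE	CG1	Hydrophobic
ILE	CG2	Hydrophobic
ILE	CD1	Hydrophobic
LEU	CB	Hydrophobic
LEU	CG	Hydrophobic
LEU	CD1	Hydrophobic
LEU	CD2	Hydrophobic
LYS	CB	Hydrophobic
LYS	CG	Hydrophobic
LYS	CD	Hydrophobic
LYS	CE	Neutral
LYS	NZ	HydrogenDonor;PositiveIonizable
MET	CB	Hydrophobic
MET	CG	Hydrophobic
MET	SD	Sulfur
MET	CE	Hydrophobic
PHE	CB	Hydrophobic
PHE	CG	Aromatic;Hydrophobic
PHE	CD1	Aromatic;Hydrophobic
PHE	CD2	Aromatic;Hydrophobic
PHE	CE1	Aromatic;Hydrophobic
PHE	CE2	Aromatic;Hydrophobic
PHE	CZ	Aromatic;Hydrophobic
PRO	CB	Hydrophobic
PRO	CG	Hydrophobic
PRO	CD	Neutral
SER	CB	Neutral
SER	OG	HydrogenDonor;HydrogenAcceptor
THR	CB	Neutral
THR	OG1	HydrogenDonor;HydrogenAcceptor
THR	CG2	Hydrophobic
TRP	CB	Hydrophobic
TRP	CG	Aromatic;Hydrophobic
TRP	CD1	Aromatic
TRP	CD2	Aromatic;Hydrophobic
TRP	NE1	Aromatic;HydrogenDonor
TRP	CE2	Aromatic
TRP	CE3	Aromatic;Hydrophobic
TRP	CZ2	Aromatic;Hydrophobic
TRP	CZ3	Aromatic;Hydrophobic
TRP	CH2	Aromatic;Hydrophobic
TYR	CB	Hydrophobic
TYR	CG	Aromatic;Hydrophobic
TYR	CD1	Aromatic;Hydrophobic
TYR	CD2	Aromatic;Hydrophobic
TYR	CE1	Aromatic;Hydrophobic
TYR	CE2	Aromatic;Hydrophobic
TYR	CZ	Aromatic;Neutral
TYR	OH	HydrogenDonor;HydrogenAcceptor
VAL	CB	Hydrophobic
VAL	CG1	Hydrophobic
VAL	CG2	Hydrophobic
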