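# Common restriction enzymes and their recognition motifs (IUPAC).
# Editable: add or remove rows (name<TAB>motif).
name	motif
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
NotI	GCGGCCGC
XhoI	CTCGAG
SalI	GTCGAC
PstI	CTGCAG
SmaI	CCCGGG
KpnI	GGTACC
SacI	GAGCTC
XbaI	TCTAGA
SpeI	ACTAGT
NcoI	CCATGG
NdeI	CATATG
BglII	AGATCT
EcoRV	GATATC
HpaII	CCGG
AluI	AGCT
DdeI	CTNAG
HinfI	GANTC
AvaI	CYCGRG
AatII	GACGTC
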