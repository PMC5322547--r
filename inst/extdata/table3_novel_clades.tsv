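class	clade	taxonomic_distribution	support
ANTP_NKL	Clade I	Trochozoa	27
ANTP_NKL	Hmx	Bivalvia	98
ANTP_NKL	engrailed	Lophotrochozoa	NA
PRD	Clade I	Trochozoa	67
PRD	Clade II	Trochozoa	82
PRD	Clade III	Protostomes	12
PRD	Clade IV	Trochozoa	39
PRD	Clade V	Lophotrochozoa	NA
PRD	Clade VI	Trochozoa	NA
LIM	Clade I	Platyhelminthes Neodermata	86
SIX	Clade I	Platyhelminthes Neodermata	30
CUT	Clade I	Lophotrochozoa	NA
TALE	Clade I	Trochozoa	99
TALE	Clade II	Bivalvia	44
TALE	Clade III	Lophotrochozoa	10
TALE	Clade IV	Lophotrochozoa	14
TALE	Clade V	Bivalvia	93
TALE	Clade VI	Mollusca	NA
TALE	Clade VII	Bivalvia	26
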