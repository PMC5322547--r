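motif	asserts	kind	min_identity	sequence
Paired	PRD	class	0.8	SRNLMGMDQTPCLGINGKYWRHDPEHMNVYAKWACKSGMVKYSCAGSDVAMDPKCFDIQP
LIM	LIM	class	0.8	YAFPTLYWYHRQTWADWQYITMKYTYRYQMPGKQSVHYGFMNEIRGLPVC
POU_specific	POU	class	0.8	SHYDKRAVCIEHKNNNIAHRVQKDMPCLQMILVGREKIDPHDLASEEYDLPGKMRHALPE
SIX	SINE	class	0.8	CSHEHLVKWGQSESQHFTDSNNLMAGRYWICTCCASMLPMKSVWDTNWCVGIQRN
CUT	CUT	class	0.8	PACFKYVITVKPKAFIEIYSQRDIYQGDDLMTWWTKALTRNQRHSSWMIFKEPDMYGVGM
PROS	PROS	class	0.8	HKHHRRIPYELTKKKNETCGTLREERVWYWQEPVCECNAHGERNERQESFFECRD
ZF	ZF	class	0.8	DFMRTAFHYKAYFFSDGETCLYNKCPKQVKHVCKQVVHGC
CERS	CERS	class	0.8	LDICKWNVVLMEQQEHGDRKSWRCPEASYDDCTRDNSTTA
PADRE	TALE Clade VI/VII	clade	0.8	DMPERRTLMGLKNSQVLMVRHGVPIINFHQPYPRPTFPGKMNSVLDSQMQAQYDELYLNDWGPPQQGLFCMECMRAQQYLDFYNWCH
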