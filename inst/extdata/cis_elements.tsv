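# Starter cis-regulatory element dictionary (PlantCARE-style consensus
# patterns, illustrative): six stress-related and seven phytohormone-related
# elements.  Users may supply their own dictionary in the same layout.
name	pattern	category
W-box	TTGAC	stress
LTR	CCGAAA	stress
TC-rich	GTTTTCTTAC	stress
MBS	CAACTG	stress
ARE	AAACCA	stress
DRE	GCCGAC	stress
ABRE	ACGTGGC	phytohormone
TCA-element	CCATCTTTTT	phytohormone
TGA-element	AACGAC	phytohormone
ERE	ATTTCAAA	phytohormone
P-box	CCTTTTG	phytohormone
CGTCA-motif	CGTCA	phytohormone
TGACG-motif	TGACG	phytohormone
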