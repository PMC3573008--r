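gene_id	gene_name	associated_sex	chromosome
ASMTL	acetylserotonin O-methyltransferase-like	male_biased	X
BIRC6	baculoviral IAP repeat-containing 6	male_biased	2
CS	citrate synthase	male_biased	12
GSTA4	glutathione S-transferase alpha 4	male_biased	6
KLK7	kallikrein-related peptidase 7	male_biased	19
PCDH11Y	protocadherin 11 Y-linked	male_biased	Y
SEMA6A	semaphorin 6A	male_biased	5
ARSD	arylsulfatase D	female_biased	X
DDX3X	DEAD box polypeptide 3, X-linked	female_biased	X
EIF1AX	eukaryotic translation initiation factor 1A, X-linked	female_biased	X
HOXB2	homeobox B2	female_biased	17
RPS4X	ribosomal protein S4, X-linked	female_biased	X
UTX	ubiquitously transcribed tetratricopeptide repeat, X chromosome	female_biased	X
XIST	X (inactive)-specific transcript	female_biased	X
ZFX	zinc finger protein, X-linked	female_biased	X
ZRSR2	zinc finger CCCH type, RNA-binding motif and serine/arginine rich 2	female_biased	X
ZXDA	zinc finger, X-linked, duplicated A	female_biased	X
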