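alias	token
COX1	COI
CO1	COI
COI	COI
COXI	COI
COX2	COII
CO2	COII
COII	COII
COX3	COIII
CO3	COIII
COIII	COIII
TRNA	trnA
TRNA-ALA	trnA
TRNALA	trnA
TRNR	trnR
TRNA-ARG	trnR
TRNARG	trnR
TRNN	trnN
TRNA-ASN	trnN
TRNASN	trnN
TRND	trnD
TRNA-ASP	trnD
TRNASP	trnD
TRNC	trnC
TRNA-CYS	trnC
TRNCYS	trnC
TRNQ	trnQ
TRNA-GLN	trnQ
TRNGLN	trnQ
TRNE	trnE
TRNA-GLU	trnE
TRNGLU	trnE
TRNG	trnG
TRNA-GLY	trnG
TRNGLY	trnG
TRNH	trnH
TRNA-HIS	trnH
TRNHIS	trnH
TRNI	trnI
TRNA-ILE	trnI
TRNILE	trnI
TRNL	trnL
TRNA-LEU	trnL
TRNLEU	trnL
TRNK	trnK
TRNA-LYS	trnK
TRNLYS	trnK
TRNM	trnM
TRNA-MET	trnM
TRNMET	trnM
TRNF	trnF
TRNA-PHE	trnF
TRNPHE	trnF
TRNP	trnP
TRNA-PRO	trnP
TRNPRO	trnP
TRNS	trnS
TRNA-SER	trnS
TRNSER	trnS
TRNT	trnT
TRNA-THR	trnT
TRNTHR	trnT
TRNW	trnW
TRNA-TRP	trnW
TRNTRP	trnW
TRNY	trnY
TRNA-TYR	trnY
TRNTYR	trnY
TRNV	trnV
TRNA-VAL	trnV
TRNVAL	trnV
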