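name	consensus
GBOX_CORE	CACGTG
GBOX_EXT	GCCACGTGGC
ABRE	YACGTGGC
ABRE_CE3	ACGCGTGTC
EBOX	CANNTG
TATABOX	TATAAAT
TATABOX2	TATTAAT
CAATBOX	CCAAT
WBOX	TTGACY
WBOX_NT	TGACY
GT1_CONSENSUS	GRWAAW
GT1_BOX	GGTTAA
IBOX	GATAAG
GATABOX	GATA
MYB_CORE	CNGTTR
MYB_PLANT	MACCWAMC
MYB_P	CCWACC
MYC_CONSENSUS	CANNTG
MYC_ATRD22	CACATG
GCCBOX	GCCGCC
AUXRE	TGTCTC
DRE_CRT	RCCGAC
DRE_CORE	ACCGAGA
LTRE	ACCGACA
RY_ELEMENT	CATGCA
SKN1_MOTIF	GTCAT
ARR1AT	NGATT
PYRIMIDINE_BOX	CCTTTT
GARE	TAACAAR
POLLEN1_LELAT	AGAAA
CAREOSREP1	CAACTC
AMYBOX1	TAACARA
AMYBOX2	TATCCAT
CIACADIANLELHC	CAANNNNATC
SEF4_MOTIF	RTTTTTR
PROLAMIN_BOX	TGCAAAG
ACGT_ELEMENT	ACGT
ASF1_MOTIF	TGACG
OCS_ELEMENT	TGACGTAAGGGATGACGCAC
SP8BF	TACTATT
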