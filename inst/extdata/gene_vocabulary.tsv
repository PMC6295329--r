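synonym	token
# identity mappings so normalization is idempotent
ND1	ND1
ND2	ND2
ND3	ND3
ND4	ND4
ND4L	ND4L
ND5	ND5
ND6	ND6
COI	COI
COII	COII
COIII	COIII
ATP6	ATP6
ATP8	ATP8
Cytb	Cytb
rrnS	rrnS
rrnL	rrnL
OL	OL
CR	CR
unknown	unknown
# NADH dehydrogenase subunits
NAD1	ND1
NAD2	ND2
NAD3	ND3
NAD4	ND4
NAD4L	ND4L
NAD5	ND5
NAD6	ND6
NADH1	ND1
NADH2	ND2
NADH3	ND3
NADH4	ND4
NADH4L	ND4L
NADH5	ND5
NADH6	ND6
NADH dehydrogenase subunit 1	ND1
NADH dehydrogenase subunit 2	ND2
NADH dehydrogenase subunit 3	ND3
NADH dehydrogenase subunit 4	ND4
NADH dehydrogenase subunit 4L	ND4L
NADH dehydrogenase subunit 5	ND5
NADH dehydrogenase subunit 6	ND6
# cytochrome c oxidase
CO1	COI
CO2	COII
CO3	COIII
COX1	COI
COX2	COII
COX3	COIII
COXI	COI
COXII	COII
COXIII	COIII
MT-CO1	COI
MT-CO2	COII
MT-CO3	COIII
cytochrome c oxidase subunit 1	COI
cytochrome c oxidase subunit I	COI
cytochrome c oxidase subunit 2	COII
cytochrome c oxidase subunit II	COII
cytochrome c oxidase subunit 3	COIII
cytochrome c oxidase subunit III	COIII
# ATP synthase
ATPase6	ATP6
ATPase8	ATP8
ATPase 6	ATP6
ATPase 8	ATP8
ATP synthase F0 subunit 6	ATP6
ATP synthase F0 subunit 8	ATP8
# cytochrome b
CYTB	Cytb
COB	Cytb
CYB	Cytb
MT-CYB	Cytb
cytochrome b	Cytb
# ribosomal RNAs
12S	rrnS
16S	rrnL
12S rRNA	rrnS
16S rRNA	rrnL
12S ribosomal RNA	rrnS
16S ribosomal RNA	rrnL
s-rRNA	rrnS
l-rRNA	rrnL
SSU rRNA	rrnS
LSU rRNA	rrnL
rrn12	rrnS
rrn16	rrnL
small subunit ribosomal RNA	rrnS
large subunit ribosomal RNA	rrnL
# light-strand replication origin
O_L	OL
OriL	OL
rep_origin	OL
rep origin	OL
L-strand origin	OL
origin of L-strand replication	OL
light strand replication origin	OL
# control region
D-loop	CR
D loop	CR
control region	CR
control_region	CR
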