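gene	allele	defining_variants	function	sv_tag	is_reference
CYP2D6	*1		normal	none	TRUE
CYP2D6	*2	22-42523943-A-G	normal	none	FALSE
CYP2D6	*4	22-42524947-C-T	no_function	none	FALSE
CYP2D6	*5		no_function	del	FALSE
CYP2D6	*9	22-42524176-GAAG-G	decreased	none	FALSE
CYP2D6	*10	22-42526694-G-A	decreased	none	FALSE
CYP2D6	*17	22-42525772-G-A	decreased	none	FALSE
CYP2D6	*29	22-42525035-G-A	decreased	none	FALSE
CYP2D6	*35	22-42526763-C-T	normal	none	FALSE
CYP2D6	*41	22-42523805-C-T	decreased	none	FALSE
CYP2D6	*106	22-42526580-C-T	unknown	none	FALSE
CYP2D6	*36+*10	22-42526694-G-A	decreased	hyb	FALSE
CYP2D6	*36x2+*10	22-42526694-G-A	decreased	hyb	FALSE
CYP2D6	*68+*4	22-42524947-C-T	no_function	hyb	FALSE
CYP2E1	*1		normal	none	TRUE
CYP2E1	*5	10-135341006-G-C	unknown	none	FALSE
CYP2E1	*7	10-135341011-T-A	unknown	none	FALSE
CYP2E1	*S1		unknown	dup	FALSE
GSTT1	*A		normal	none	TRUE
GSTT1	*0		no_function	del	FALSE
GSTM1	*A		normal	none	TRUE
GSTM1	*B	1-110233000-G-C	normal	none	FALSE
GSTM1	*0		no_function	del	FALSE
UGT2B17	*1		normal	none	TRUE
UGT2B17	*2		no_function	del	FALSE
CYP2A6	*1		normal	none	TRUE
CYP2A6	*2	19-41354533-T-A	no_function	none	FALSE
CYP2A6	*9	19-41356379-A-C	decreased	none	FALSE
CYP2A6	*4		no_function	del	FALSE
CYP2B6	*1		normal	none	TRUE
CYP2B6	*4	19-41515263-A-G	increased	none	FALSE
CYP2B6	*6	19-41512841-G-T,19-41515263-A-G	decreased	none	FALSE
CYP2B6	*8	19-41512869-A-G	no_function	none	FALSE
CYP2B6	*9	19-41512841-G-T	decreased	none	FALSE
CYP2B6	*29		no_function	hyb	FALSE
UGT1A1	*1		normal	none	TRUE
UGT1A1	*6	2-234669144-G-A	decreased	none	FALSE
UGT1A1	*28	2-234668879-C-CAT	decreased	none	FALSE
UGT1A1	*36	2-234668879-CAT-C	increased	none	FALSE
UGT1A1	*37	2-234668879-C-CATAT	decreased	none	FALSE
UGT1A1	*80	2-234665782-C-T	decreased	none	FALSE
UGT1A1	*80+*28	2-234665782-C-T,2-234668879-C-CAT	decreased	none	FALSE
UGT1A1	*80+*37	2-234665782-C-T,2-234668879-C-CATAT	decreased	none	FALSE
UGT2B15	*1		normal	none	TRUE
UGT2B15	*2	4-69512937-G-T	decreased	none	FALSE
UGT2B15	*4	4-69512847-T-G,4-69536084-A-C	decreased	none	FALSE
UGT2B15	*5	4-69515000-C-T	unknown	none	FALSE
UGT2B15	*S1		no_function	del	FALSE
SLC22A2	*1		normal	none	TRUE
SLC22A2	*2	6-160670282-G-A	unknown	none	FALSE
SLC22A2	*3	6-160665000-C-T	unknown	none	FALSE
SLC22A2	*S1		unknown	del	FALSE
SLC22A2	*S2		unknown	del	FALSE
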