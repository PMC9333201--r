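gene	allele	function	activity_value
CYP2D6	*1	normal	1
CYP2D6	*2	normal	1
CYP2D6	*4	no_function	0
CYP2D6	*5	no_function	0
CYP2D6	*6	no_function	0
CYP2D6	*9	decreased	0.5
CYP2D6	*10	decreased	0.25
CYP2D6	*14	no_function	0
CYP2D6	*15	no_function	0
CYP2D6	*17	decreased	0.5
CYP2D6	*21	no_function	0
CYP2D6	*29	decreased	0.5
CYP2D6	*35	normal	1
CYP2D6	*36+*10	decreased	0.25
CYP2D6	*36x2+*10	decreased	0.25
CYP2D6	*40	no_function	0
CYP2D6	*41	decreased	0.5
CYP2D6	*45	normal	1
CYP2D6	*46	uncertain	NA
CYP2D6	*68+*4	no_function	0
CYP2D6	*71	uncertain	NA
CYP2D6	*106	unknown	NA
CYP2C9	*1	normal	1
CYP2C9	*2	decreased	0.5
CYP2C9	*3	no_function	0
CYP2C9	*5	no_function	0
CYP2C9	*6	no_function	0
CYP2C9	*8	decreased	0.5
CYP2C9	*9	uncertain	NA
CYP2C9	*11	decreased	0.5
CYP2C9	*61	decreased	0.5
DPYD	Reference	normal	1
DPYD	c.85T>C (*9A)	normal	1
DPYD	c.496A>G	uncertain	NA
DPYD	c.557A>G	uncertain	NA
DPYD	c.1218G>A	uncertain	NA
DPYD	c.1349C>T	uncertain	NA
DPYD	c.1601G>A (*4)	normal	1
DPYD	c.1627A>G (*5)	normal	1
DPYD	c.1682G>T	uncertain	NA
DPYD	c.1896T>C	uncertain	NA
DPYD	c.2194G>A (*6)	normal	1
DPYD	c.2846A>T	decreased	0.5
CYP2B6	*1	normal	NA
CYP2B6	*2	uncertain	NA
CYP2B6	*4	increased	NA
CYP2B6	*5	normal	NA
CYP2B6	*6	decreased	NA
CYP2B6	*8	no_function	NA
CYP2B6	*9	decreased	NA
CYP2B6	*15	no_function	NA
CYP2B6	*17	uncertain	NA
CYP2B6	*18	no_function	NA
CYP2B6	*20	uncertain	NA
CYP2B6	*22	increased	NA
CYP2B6	*23	uncertain	NA
CYP2B6	*29	no_function	NA
CYP2C19	*1	normal	NA
CYP2C19	*2	no_function	NA
CYP2C19	*3	no_function	NA
CYP2C19	*4	no_function	NA
CYP2C19	*6	no_function	NA
CYP2C19	*8	no_function	NA
CYP2C19	*13	normal	NA
CYP2C19	*15	normal	NA
CYP2C19	*17	increased	NA
CYP2C19	*35	no_function	NA
CYP2C19	*39	uncertain	NA
CYP3A5	*1	normal	NA
CYP3A5	*3	no_function	NA
CYP3A5	*6	no_function	NA
CYP3A5	*7	no_function	NA
TPMT	*1	normal	NA
TPMT	*3C	no_function	NA
TPMT	*8	decreased	NA
TPMT	*16	uncertain	NA
SLCO1B1	*1A	normal	NA
SLCO1B1	*1B	normal	NA
SLCO1B1	*5	decreased	NA
SLCO1B1	*14	increased	NA
SLCO1B1	*15	decreased	NA
SLCO1B1	*17	uncertain	NA
SLCO1B1	*20	uncertain	NA
SLCO1B1	*21	uncertain	NA
SLCO1B1	*24	uncertain	NA
SLCO1B1	*27	uncertain	NA
SLCO1B1	*30	uncertain	NA
SLCO1B1	*31	uncertain	NA
SLCO1B1	*32	uncertain	NA
SLCO1B1	*S1	unknown	NA
SLCO1B1	*S2	unknown	NA
UGT1A1	*1	normal	NA
UGT1A1	*6	decreased	NA
UGT1A1	*28	decreased	NA
UGT1A1	*36	increased	NA
UGT1A1	*37	decreased	NA
UGT1A1	*80	decreased	NA
UGT1A1	*80+*28	decreased	NA
UGT1A1	*80+*37	decreased	NA
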