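gene	label	lower	upper
CYP2D6	poor metabolizer	-1	0
CYP2D6	intermediate metabolizer	0	1
CYP2D6	normal metabolizer	1	2.25
CYP2D6	ultrarapid metabolizer	2.25	Inf
CYP2C9	poor metabolizer	-1	0.5
CYP2C9	intermediate metabolizer	0.5	1.5
CYP2C9	normal metabolizer	1.5	Inf
DPYD	poor metabolizer	-1	0.5
DPYD	intermediate metabolizer	0.5	1.5
DPYD	normal metabolizer	1.5	Inf
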