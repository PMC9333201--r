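gene	func_a	func_b	label
CYP2B6	normal	normal	normal metabolizer
CYP2B6	decreased	normal	intermediate metabolizer
CYP2B6	no_function	normal	intermediate metabolizer
CYP2B6	decreased	decreased	intermediate metabolizer
CYP2B6	decreased	no_function	poor metabolizer
CYP2B6	no_function	no_function	poor metabolizer
CYP2B6	increased	normal	rapid metabolizer
CYP2B6	increased	increased	ultrarapid metabolizer
CYP2B6	decreased	increased	normal metabolizer
CYP2B6	increased	no_function	intermediate metabolizer
CYP2C19	normal	normal	normal metabolizer
CYP2C19	increased	normal	rapid metabolizer
CYP2C19	increased	increased	ultrarapid metabolizer
CYP2C19	no_function	normal	intermediate metabolizer
CYP2C19	increased	no_function	intermediate metabolizer
CYP2C19	no_function	no_function	poor metabolizer
CYP3A5	normal	normal	normal metabolizer
CYP3A5	no_function	normal	intermediate metabolizer
CYP3A5	no_function	no_function	poor metabolizer
TPMT	normal	normal	normal metabolizer
TPMT	decreased	normal	intermediate metabolizer
TPMT	no_function	normal	intermediate metabolizer
TPMT	decreased	decreased	poor metabolizer
TPMT	decreased	no_function	poor metabolizer
TPMT	no_function	no_function	poor metabolizer
UGT1A1	normal	normal	normal metabolizer
UGT1A1	increased	increased	normal metabolizer
UGT1A1	increased	normal	normal metabolizer
UGT1A1	decreased	normal	intermediate metabolizer
UGT1A1	decreased	increased	intermediate metabolizer
UGT1A1	decreased	decreased	poor metabolizer
SLCO1B1	normal	normal	normal function
SLCO1B1	decreased	normal	decreased function
SLCO1B1	decreased	decreased	poor function
SLCO1B1	increased	normal	increased function
SLCO1B1	increased	increased	increased function
SLCO1B1	decreased	increased	normal function
SLCO1B1	increased	no_function	decreased function
SLCO1B1	no_function	normal	decreased function
SLCO1B1	no_function	no_function	poor function
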