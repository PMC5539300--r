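# Default two-level TE taxonomy (type within class).
# A stand-in for the full 68-type canonical repeat taxonomy; covers the types
# used by this package's analyses and simulations.
# n_types: 11
te_type	te_class
Alu	SINE
MIR	SINE
L1	LINE
L2	LINE
ERV1	LTR
ERV3	LTR
ERVK	LTR
ERVL	LTR
Endogenous Retrovirus	LTR
LTR Retrotransposon	LTR
SAT	Satellite
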