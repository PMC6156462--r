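type	g1	g3	g4
VIII	6	*	*
II	7	*	*
nsLTPy	8	*	*
VI	10	*	*
IX	13	*	*
V	14	*	*
I	9	19,20	*
XI	9	13	*
III	9	9	12
IV	9	9,12	22-24
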