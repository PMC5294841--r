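family	type
# type signature genes
cas3	I
cas9	II
cas10	III
csf1	IV
cpf1	V
cas12a	V
# type I module subunits
cas8a	I
cas8b	I
cas8c	I
cas8e	I
cas8f	I
cse1	I
cse2	I
csy1	I
csy2	I
csy3	I
cas6e	I
cas6f	I
# type II
csn2	II
# type III module subunits
csm2	III
csm3	III
csm4	III
csm5	III
cmr1	III
cmr3	III
cmr4	III
cmr5	III
cmr6	III
# type IV
csf2	IV
csf3	IV
csf4	IV
csf5	IV
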