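protein	stage
MK_G1_1	G1
MK_G1_2	G1
MK_G1_3	G1
MK_G1_4	G1
MK_G1_5	G1
MK_G1_6	G1
MK_G1_7	G1
MK_G1_8	G1
MK_S_1	S
MK_S_2	S
MK_S_3	S
MK_S_4	S
MK_S_5	S
MK_S_6	S
MK_S_7	S
MK_S_8	S
MK_G2M_1	G2M
MK_G2M_2	G2M
MK_G2M_3	G2M
MK_G2M_4	G2M
MK_G2M_5	G2M
MK_G2M_6	G2M
MK_G2M_7	G2M
MK_G2M_8	G2M
MK_prophase_1	prophase
MK_prophase_2	prophase
MK_prophase_3	prophase
MK_prophase_4	prophase
MK_prophase_5	prophase
MK_prophase_6	prophase
MK_prophase_7	prophase
MK_prophase_8	prophase
MK_prometaphase_1	prometaphase
MK_prometaphase_2	prometaphase
MK_prometaphase_3	prometaphase
MK_prometaphase_4	prometaphase
MK_prometaphase_5	prometaphase
MK_prometaphase_6	prometaphase
MK_prometaphase_7	prometaphase
MK_prometaphase_8	prometaphase
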