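cross_id	seed_genotype	count
SC1_M	S_x/S_C1	0
SC1_M	S_C1/S_C1	0
SC1_M	S_x/S_y	67
SC1_M	S_C1/S_y	44
S7_Rm	S_8/S_7	0
S7_Rm	S_7/S_7	0
S7_Rm	S_8/S_6	10
S7_Rm	S_7/S_6	16
S9_M	S_x/S_9	0
S9_M	S_9/S_9	0
S9_M	S_x/S_y	26
S9_M	S_9/S_y	24
S11_M	S_x/S_11	0
S11_M	S_11/S_11	0
S11_M	S_x/S_y	27
S11_M	S_11/S_y	21
S13_M	S_x/S_13	0
S13_M	S_13/S_13	0
S13_M	S_x/S_y	23
S13_M	S_13/S_y	27
SC2_TF	S_21/S_C2	0
SC2_TF	S_C2/S_C2	0
SC2_TF	S_21/S_C1	35
SC2_TF	S_C2/S_C1	25
S6_M	S_x/S_6	0
S6_M	S_6/S_6	0
S6_M	S_x/S_y	26
S6_M	S_6/S_y	23
S10_M	S_x/S_10	0
S10_M	S_10/S_10	0
S10_M	S_x/S_y	30
S10_M	S_10/S_y	17
S12_Rm	S_13/S_12	0
S12_Rm	S_12/S_12	0
S12_Rm	S_13/S_9	13
S12_Rm	S_12/S_9	15
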