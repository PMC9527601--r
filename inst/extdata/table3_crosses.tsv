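cross_id	mother_id	mother_genotype	father_id	father_genotype	shared_allele
SC1_M	M1	S_x/S_C1	M2	S_C1/S_y	S_C1
S7_Rm	Rm09	S_8/S_7	Rm08	S_7/S_6	S_7
S9_M	M3	S_x/S_9	M4	S_9/S_y	S_9
S11_M	M5	S_x/S_11	M6	S_11/S_y	S_11
S13_M	M7	S_x/S_13	M8	S_13/S_y	S_13
SC2_TF	TF	S_21/S_C2	OB	S_C2/S_C1	S_C2
S6_M	M9	S_x/S_6	M10	S_6/S_y	S_6
S10_M	M11	S_x/S_10	M12	S_10/S_y	S_10
S12_Rm	Rm32	S_13/S_12	Rm33	S_12/S_9	S_12
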