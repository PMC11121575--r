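Alzheimer Disease	synthetic demo set: every multimorbid gene	MAPT	PSEN1	APP	APOE	A2M	ABCA7	PLAU	PSEN2	MPO	COL18A1	SYNJ1	HFE	NOS3	SORL1	NOTCH2	TGFB2	LAMA1
Dementia	synthetic demo set	MAPT	PSEN1	APP	APOE	A2M	ABCA7	PLAU	PSEN2	MPO	COL18A1	SYNJ1	HFE	NOS3	TGFB2	LAMA1
Type 2 diabetes	synthetic demo set	NOTCH2	LAMA1
Hypertension	synthetic demo set	HFE	NOS3	NOTCH2	TGFB2
Parkinson's disease	synthetic demo set	MAPT	PSEN1	APP	APOE	A2M	ABCA7	PLAU	PSEN2	MPO	HFE	NOS3	SORL1
Down syndrome	synthetic demo set	MAPT	PSEN1	APP	APOE	COL18A1	SYNJ1	SORL1
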