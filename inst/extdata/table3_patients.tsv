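patient_id	site	histology	ps	treatment	platinum_response	pfs_days	pfs_event	reported_prediction
Ovarian #2	ovary		1	olaparib	missing	240	TRUE	S
Ovarian #6	ovary		1	olaparib	missing	224	TRUE	S
Ovarian #20	ovary		2	olaparib	missing	368	TRUE	S
Ovarian #23	ovary		1	olaparib	missing	93	TRUE	S or R
Breast #6	breast		1	olaparib	missing	136	TRUE	S
Breast #8	breast		2	olaparib	missing	144	TRUE	S
Digestive tract #1 (colon)	digestive_tract		1	olaparib	missing	36	TRUE	R
Digestive tract #2 (pancreas)	digestive_tract		3	olaparib	missing	12	TRUE	R
Digestive tract #5 (pancreas)	digestive_tract		0	olaparib	missing	54	TRUE	R
Digestive tract #6 (pancreas)	digestive_tract		1	olaparib	missing	12	TRUE	R
Digestive tract #7 (pancreas)	digestive_tract		3	olaparib	missing	27	TRUE	R
Skin #1	skin		1	olaparib	missing	210	TRUE	S
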