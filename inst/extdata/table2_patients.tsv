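patient_id	site	histology	ps	treatment	platinum_response	pfs_days	pfs_event	pfs_note
Ovarian #1	ovary		NA	olaparib	missing	1218	FALSE	still under olaparib
Ovarian #2	ovary		1	olaparib	missing	240	TRUE
Ovarian #3	ovary		NA	olaparib	missing	953	TRUE
Ovarian #4	ovary		NA	olaparib	missing	441	TRUE
Ovarian #5	ovary		NA	olaparib	missing	59	TRUE
Ovarian #6	ovary		1	olaparib	missing	224	TRUE
Ovarian #7	ovary		NA	olaparib	missing	1659	FALSE	still under olaparib
Ovarian #8	ovary		NA	olaparib	missing	81	TRUE
Ovarian #9	ovary		NA	olaparib	missing	910	TRUE
Ovarian #10	ovary		NA	olaparib	missing	94	TRUE
Ovarian #11	ovary		NA	olaparib	missing	1359	FALSE	still under olaparib
Ovarian #12	ovary		NA	olaparib	missing	58	TRUE
Ovarian #13	ovary		NA	olaparib	missing	120	TRUE
Ovarian #14	ovary		NA	olaparib	missing	101	TRUE	re-treated patient, first episode
Ovarian #15	ovary		NA	olaparib	missing	168	TRUE	re-treated patient, second episode
Ovarian #16	ovary		NA	olaparib	missing	79	TRUE
Ovarian #17	ovary		NA	olaparib	missing	614	TRUE
Ovarian #18	ovary		NA	olaparib	missing	636	TRUE
Ovarian #19	ovary		NA	olaparib	missing	1	FALSE	allergic reaction
Ovarian #20	ovary		2	olaparib	missing	368	TRUE
Ovarian #21	ovary		NA	olaparib	missing	288	TRUE
Ovarian #22	ovary		NA	olaparib	missing	306	TRUE
Ovarian #23	ovary		1	olaparib	missing	93	TRUE
Breast #1	breast		NA	olaparib	missing	231	TRUE
Breast #2	breast		NA	olaparib	missing	98	TRUE
Breast #3	breast		NA	olaparib	missing	190	TRUE
Breast #4	breast		NA	olaparib	missing	223	TRUE
Breast #5	breast		NA	olaparib	missing	1212	FALSE	still under olaparib
Breast #6	breast		1	olaparib	missing	136	TRUE
Breast #7	breast		NA	olaparib	missing	116	TRUE
Breast #8	breast		2	olaparib	missing	144	TRUE
Digestive tract #1 (colon)	digestive_tract		1	olaparib	missing	36	TRUE
Digestive tract #2 (pancreas)	digestive_tract		3	olaparib	missing	12	TRUE
Digestive tract #3 (pancreas)	digestive_tract		NA	olaparib	missing	64	TRUE
Digestive tract #4 (rectum)	digestive_tract		NA	olaparib	missing	62	TRUE
Digestive tract #5 (pancreas)	digestive_tract		0	olaparib	missing	54	TRUE
Digestive tract #6 (pancreas)	digestive_tract		1	olaparib	missing	12	TRUE
Digestive tract #7 (pancreas)	digestive_tract		3	olaparib	missing	27	TRUE
Digestive tract #8 (pancreas)	digestive_tract		NA	olaparib	missing	20	TRUE
Endometrium #1	endometrium	clear cell adenocarcinoma	NA	olaparib	missing	190	TRUE
Skin #1	skin	basal cell carcinoma	1	olaparib	missing	210	TRUE
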