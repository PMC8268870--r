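patient_id	site	histology	ps	treatment	platinum_response	pfs_days	pfs_event	reported_prediction
Niraparib #1	ovary	high grade serous adenocarcinoma	1	niraparib	missing	392	TRUE	S
Niraparib #2	ovary	high grade serous adenocarcinoma	1	niraparib	missing	176	TRUE	S
Niraparib #3	ovary	high grade serous adenocarcinoma	1	niraparib	missing	113	TRUE	S
Niraparib #4	ovary	high grade serous adenocarcinoma	1	niraparib	missing	342	TRUE	R
Niraparib #5	ovary	high grade serous adenocarcinoma	2	niraparib	missing	84	TRUE	R
Niraparib #6	ovary	high grade serous adenocarcinoma	1	niraparib	missing	87	TRUE	R
Niraparib #7	ovary	high grade serous adenocarcinoma	1	niraparib	missing	469	TRUE	R
Niraparib #8	ovary	high grade serous adenocarcinoma	1	niraparib	missing	63	TRUE	U
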