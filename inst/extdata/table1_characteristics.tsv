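characteristic	n_percent	median_age_or_days
Age at olaparib treatment	41	63 (31-84)
Ovary	23 (56.2%)	63 (43-84)
Breast	8 (19.5%)	62 (31-83)
Digestive tract	8 (19.5%)	62 (50-76)
Digestive tract detail (pancreas, colon, rectum)	(5, 2, 1)
Endometrium	1 (2.4%)	56
Skin	1 (2.4%)	73
Adenocarcinoma (breast, digestive tract)	16 (39%)
High-grade serous adenocarcinoma	22 (53.8%)
Clear cell adenocarcinoma	1 (2.4%)
Basal cell carcinoma	1 (2.4%)
Unknown histology	1 (2.4%)
Number of patients treated with platinum salts	39 (92.9%)
Platinum progression-free survival	NA	126 (30-637)
Platinum PFS < 90 days	7 (18%)
Platinum PFS > 90 days	32 (82%)
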