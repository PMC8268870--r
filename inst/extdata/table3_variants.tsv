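patient_id	gene	cdna	protein	known_class	vaf	purity	provean_score	provean_call	dann_score	dann_call	second_hit_score	second_hit_call	second_hit_zone
Ovarian #2	BRCA1	c.53T > C	p.Met18Thr	unknown	NA	NA	NA	D	NA	D	0.19	B	Red
Ovarian #6	PALB2	c.656A > G	p.Asp219Gly	unknown	NA	NA	NA	B	NA	B	1.12	D	Green
Ovarian #20	BRCA1	c.2744C > T	p.Ser915Phe	unknown	NA	NA	NA	D	NA	D	0.14	B	Red
Ovarian #23	BRCA2	c.1690T > C	p.Met990Lys	unknown	NA	NA	NA	D	NA	B	0.26	B	Red
Breast #6	BRCA1	c.2783G > T	p.Gly928Val	unknown	NA	NA	NA	D	NA	U	1.04	D	Green
Breast #8	BRCA2	c.4860A > T	p.Leu1620Phe	unknown	NA	NA	NA	D	NA	B	0.44	B	Red
Breast #8	RAD51D	c.328G > A	p.Asp110Asn	unknown	NA	NA	NA	D	NA	D	0.16	B	Red
Digestive tract #1 (colon)	PALB2	c.2719G > A	p.Glu907Lys	unknown	NA	NA	NA	B	NA	B	0.66	B	Red
Digestive tract #2 (pancreas)	BRCA1	c.2521C > T	p.Arg841Trp	unknown	NA	NA	NA	D	NA	B	1.48	D	Green
Digestive tract #2 (pancreas)	UIMC1	c.1690T > C	p.Tyr564His	unknown	NA	NA	NA	D	NA	D	0.91	D	Green
Digestive tract #5 (pancreas)	BRCA1	c.5128A > C	p.Met1710Leu	unknown	NA	NA	NA	B	NA	B	0.34	B	Red
Digestive tract #6 (pancreas)	BRCA1	c.5295A > C	p.Glu1786Asp	unknown	NA	NA	NA	B	NA	U	0.27	B	Red
Digestive tract #7 (pancreas)	BRIP1	c.3G > A	p.Met1?	unknown	NA	NA	NA	U	NA	U	0.96	D	Green
Skin #1	PALB2	c.2431C > T	p.Pro811Ser	unknown	NA	NA	NA	B	NA	B	0.53	B	Red
Skin #1	RAD50	c.3041A > G	p.Gln1014Arg	unknown	NA	NA	NA	B	NA	B	0.54	B	Red
Skin #1	RAD51C	c.584C > T	p.Ala195Val	unknown	NA	NA	NA	B	NA	D	0.72	D	Green
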