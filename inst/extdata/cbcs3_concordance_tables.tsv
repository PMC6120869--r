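table_id	task	stratum	weighting	comparison	positive_class	a	b	c	d
grade_pathologists	grade	overall	NA	pathologist1_vs_pathologist2	high	113	23	4	102
grade_image	grade	overall	uniform_class	image_vs_pathologist	high	118	8	45	117
er_overall_unweighted	er	overall	uniform_class	image_vs_ihc	positive	260	80	83	572
er_overall_grade_trained	er	overall	grade_by_class	image_vs_ihc	positive	246	104	97	548
er_lowint_unweighted	er	low-intermediate	uniform_class	image_vs_ihc	positive	21	24	25	467
er_lowint_grade_trained	er	low-intermediate	grade_by_class	image_vs_ihc	positive	28	69	18	422
er_high_unweighted	er	high	uniform_class	image_vs_ihc	positive	239	46	58	104
er_high_grade_trained	er	high	grade_by_class	image_vs_ihc	positive	218	35	79	125
basal_overall	basal	overall	grade_by_class	image_vs_pam50	non-basal	131	101	48	368
basal_lowint	basal	low-intermediate	grade_by_class	image_vs_pam50	non-basal	11	41	4	245
basal_high	basal	high	grade_by_class	image_vs_pam50	non-basal	120	60	44	123
ror_overall	ror	overall	uniform_class	image_vs_rorpt	high	342	40	118	148
ror_lowint	ror	low-intermediate	uniform_class	image_vs_rorpt	high	245	16	26	14
ror_high	ror	high	uniform_class	image_vs_rorpt	high	97	24	92	134
histology_overall	histology	overall	uniform_class	image_vs_pathologist	lobular	710	24	28	58
histology_lowint	histology	low-intermediate	uniform_class	image_vs_pathologist	lobular	268	24	23	58
histology_high	histology	high	uniform_class	image_vs_pathologist	lobular	442	0	5	0
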