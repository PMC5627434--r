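merged_group	abbreviation	n_samples
Adipose subcutaneous	ADS	380
Adipose visceral	ADV	234
Adrenal gland	ARG	159
Artery aorta	ATA	247
Artery coronary	ATC	140
Artery tibial	ATT	357
Brain other	BRO	779
Brain cerebellum	BRC	254
Brain basal ganglia	BRB	360
Breast	BST	217
Lymphoblastoid cell line	LCL	132
Fibroblast cell line	FIB	305
Colon sigmoid	CLS	173
Colon transverse	CLT	203
Gastroesophageal junction	GEJ	176
Esophagus mucosa	EMC	330
Esophagus muscularis	EMS	283
Heart atrial appendage	HRA	217
Heart left ventricle	HRV	267
Kidney cortex	KDN	36
Liver	LVR	137
Lung	LNG	360
Minor salivary gland	MSG	70
Skeletal muscle	SMU	469
Tibial nerve	TNV	334
Ovary	OVR	108
Pancreas	PNC	193
Pituitary	PIT	124
Prostate	PRS	119
Skin	SKN	661
Intestine terminal ileum	ITI	104
Spleen	SPL	118
Stomach	STM	204
Testis	TST	199
Thyroid	THY	355
Uterus	UTR	90
Vagina	VGN	97
Whole blood	WBL	444
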