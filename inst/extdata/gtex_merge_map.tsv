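sub_site	merged_group	abbreviation
Adipose - Subcutaneous	Adipose subcutaneous	ADS
Adipose - Visceral (Omentum)	Adipose visceral	ADV
Adrenal Gland	Adrenal gland	ARG
Artery - Aorta	Artery aorta	ATA
Artery - Coronary	Artery coronary	ATC
Artery - Tibial	Artery tibial	ATT
Brain - Amygdala	Brain other	BRO
Brain - Anterior cingulate cortex (BA24)	Brain other	BRO
Brain - Cortex	Brain other	BRO
Brain - Frontal Cortex (BA9)	Brain other	BRO
Brain - Hippocampus	Brain other	BRO
Brain - Hypothalamus	Brain other	BRO
Brain - Spinal cord (cervical c-1)	Brain other	BRO
Brain - Substantia nigra	Brain other	BRO
Brain - Cerebellar Hemisphere	Brain cerebellum	BRC
Brain - Cerebellum	Brain cerebellum	BRC
Brain - Caudate (basal ganglia)	Brain basal ganglia	BRB
Brain - Nucleus accumbens (basal ganglia)	Brain basal ganglia	BRB
Brain - Putamen (basal ganglia)	Brain basal ganglia	BRB
Breast - Mammary Tissue	Breast	BST
Cells - EBV-transformed lymphocytes	Lymphoblastoid cell line	LCL
Cells - Transformed fibroblasts	Fibroblast cell line	FIB
Colon - Sigmoid	Colon sigmoid	CLS
Colon - Transverse	Colon transverse	CLT
Esophagus - Gastroesophageal Junction	Gastroesophageal junction	GEJ
Esophagus - Mucosa	Esophagus mucosa	EMC
Esophagus - Muscularis	Esophagus muscularis	EMS
Heart - Atrial Appendage	Heart atrial appendage	HRA
Heart - Left Ventricle	Heart left ventricle	HRV
Kidney Cortex	Kidney cortex	KDN
Liver	Liver	LVR
Lung	Lung	LNG
Minor Salivary Gland	Minor salivary gland	MSG
Muscle - Skeletal	Skeletal muscle	SMU
Nerve - Tibial	Tibial nerve	TNV
Ovary	Ovary	OVR
Pancreas	Pancreas	PNC
Pituitary	Pituitary	PIT
Prostate	Prostate	PRS
Skin - Not Sun Exposed (Suprapubic)	Skin	SKN
Skin - Sun Exposed (Lower leg)	Skin	SKN
Small Intestine - Terminal Ileum	Intestine terminal ileum	ITI
Spleen	Spleen	SPL
Stomach	Stomach	STM
Testis	Testis	TST
Thyroid	Thyroid	THY
Uterus	Uterus	UTR
Vagina	Vagina	VGN
Whole Blood	Whole blood	WBL
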