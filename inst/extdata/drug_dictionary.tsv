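synonym	generic	class
BENAZEPRIL	benazepril	ACEI
BENAZEPRIL HYDROCHLORIDE	benazepril	ACEI
LOTENSIN	benazepril	ACEI
CAPTOPRIL	captopril	ACEI
CAPOTEN	captopril	ACEI
ENALAPRIL	enalapril	ACEI
ENALAPRIL MALEATE	enalapril	ACEI
VASOTEC	enalapril	ACEI
FOSINOPRIL	fosinopril	ACEI
FOSINOPRIL SODIUM	fosinopril	ACEI
MONOPRIL	fosinopril	ACEI
LISINOPRIL	lisinopril	ACEI
PRINIVIL	lisinopril	ACEI
ZESTRIL	lisinopril	ACEI
MOEXIPRIL	moexipril	ACEI
UNIVASC	moexipril	ACEI
PERINDOPRIL	perindopril	ACEI
PERINDOPRIL ERBUMINE	perindopril	ACEI
ACEON	perindopril	ACEI
COVERSYL	perindopril	ACEI
QUINAPRIL	quinapril	ACEI
ACCUPRIL	quinapril	ACEI
RAMIPRIL	ramipril	ACEI
ALTACE	ramipril	ACEI
TRANDOLAPRIL	trandolapril	ACEI
MAVIK	trandolapril	ACEI
IRBESARTAN	irbesartan	ARB
AVAPRO	irbesartan	ARB
HYDROCHLOROTHIAZIDE	hydrochlorothiazide	thiazide
HCTZ	hydrochlorothiazide	thiazide
MICROZIDE	hydrochlorothiazide	thiazide
CHLOROTHIAZIDE	chlorothiazide	thiazide
DIURIL	chlorothiazide	thiazide
BENDROFLUMETHIAZIDE	bendroflumethiazide	thiazide
INDAPAMIDE	indapamide	thiazide
METFORMIN	metformin	antidiabetic
METFORMIN HYDROCHLORIDE	metformin	antidiabetic
GLUCOPHAGE	metformin	antidiabetic
GLIPIZIDE	glipizide	antidiabetic
GLUCOTROL	glipizide	antidiabetic
INSULIN GLARGINE	insulin glargine	antidiabetic
LANTUS	insulin glargine	antidiabetic
ATORVASTATIN	atorvastatin	other
LIPITOR	atorvastatin	other
SIMVASTATIN	simvastatin	other
ZOCOR	simvastatin	other
OMEPRAZOLE	omeprazole	other
PRILOSEC	omeprazole	other
ASPIRIN	aspirin	other
ACETYLSALICYLIC ACID	aspirin	other
METOPROLOL	metoprolol	other
LOPRESSOR	metoprolol	other
AMLODIPINE	amlodipine	other
NORVASC	amlodipine	other
ATENOLOL	atenolol	other
TENORMIN	atenolol	other
WARFARIN	warfarin	other
COUMADIN	warfarin	other
LEVOTHYROXINE	levothyroxine	other
SYNTHROID	levothyroxine	other
IBUPROFEN	ibuprofen	other
ADVIL	ibuprofen	other
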