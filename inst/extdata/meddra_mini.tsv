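pt_code	pt_name	hlt_code	hlt_name
10001001	Lung adenocarcinoma	20000100	Lower respiratory tract neoplasms
10001002	Lung squamous cell carcinoma	20000100	Lower respiratory tract neoplasms
10001003	Small cell lung cancer	20000100	Lower respiratory tract neoplasms
10001004	Non-small cell lung cancer	20000100	Lower respiratory tract neoplasms
10001005	Lung neoplasm malignant	20000100	Lower respiratory tract neoplasms
10001006	Bronchial carcinoma	20000100	Lower respiratory tract neoplasms
10001007	Carcinoid tumour pulmonary	20000100	Lower respiratory tract neoplasms
10001008	Leukaemic infiltration pulmonary	20000100	Lower respiratory tract neoplasms
10001009	Endobronchial lipoma	20000100	Lower respiratory tract neoplasms
10001010	Benign respiratory tract neoplasm	20000100	Lower respiratory tract neoplasms
10001011	Benign lung neoplasm	20000100	Lower respiratory tract neoplasms
10001012	Metastases to lung	20000100	Lower respiratory tract neoplasms
10002001	Laryngeal cancer	20000200	Upper respiratory tract neoplasms
10002002	Pharyngeal neoplasm	20000200	Upper respiratory tract neoplasms
10003001	Diabetes mellitus	20000300	Diabetes mellitus (incl subtypes)
10003002	Type 2 diabetes mellitus	20000300	Diabetes mellitus (incl subtypes)
10003003	Type 1 diabetes mellitus	20000300	Diabetes mellitus (incl subtypes)
10004001	Hypertension	20000400	Vascular hypertensive disorders NEC
10004002	Essential hypertension	20000400	Vascular hypertensive disorders NEC
10005001	Cough	20000500	Coughing and associated symptoms
10005002	Productive cough	20000500	Coughing and associated symptoms
10006001	Headache	20000600	Headaches NEC
10006002	Migraine	20000600	Headaches NEC
10007001	Nausea	20000700	Nausea and vomiting symptoms
10007002	Vomiting	20000700	Nausea and vomiting symptoms
10008001	Cardiac failure	20000800	Heart failures NEC
10008002	Cardiac failure congestive	20000800	Heart failures NEC
10009001	Dizziness	20000900	Neurological signs and symptoms NEC
10009002	Syncope	20000900	Neurological signs and symptoms NEC
10010001	Product used for unknown indication	20001000	Therapeutic procedures NEC
10010002	Rash	20001100	Rashes, eruptions and exanthems NEC
10010003	Pruritus	20001100	Rashes, eruptions and exanthems NEC
10010004	Renal impairment	20001200	Renal failure and impairment
10010005	Acute kidney injury	20001200	Renal failure and impairment
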