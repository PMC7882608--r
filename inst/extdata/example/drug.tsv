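report_id	verbatim_name	role
R0001	LISINOPRIL 10MG TABLET	suspect
R0001	NORVASC	concomitant
R0002	HYDROCHLOROTHIAZIDE 25 MG	suspect
R0003	AVAPRO	suspect
R0003	METFORMIN HCL 500MG	concomitant
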