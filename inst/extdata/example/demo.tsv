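report_id	version	sex	age_group	country	receipt_year	receipt_quarter	outcomes
R0001	1	male	45-64	US	2015	2	hospitalization
R0002	1	female	65-74	DE	2012	3
R0003	1	unknown	unknown	GB	2018	1	death
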