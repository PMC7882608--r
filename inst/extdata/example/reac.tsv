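report_id	pt_code
R0001	10001001
R0001	10005001
R0002	10006001
R0003	10001012
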