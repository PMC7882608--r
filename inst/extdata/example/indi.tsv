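report_id	pt_code
R0001	10004001
R0002	10004001
R0003	10003002
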