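country	region
US	America
CA	America
MX	America
BR	America
AR	America
CL	America
CO	America
PE	America
VE	America
GB	Europe
DE	Europe
FR	Europe
IT	Europe
ES	Europe
NL	Europe
BE	Europe
CH	Europe
AT	Europe
SE	Europe
NO	Europe
DK	Europe
FI	Europe
IE	Europe
PT	Europe
PL	Europe
CZ	Europe
GR	Europe
HU	Europe
RO	Europe
RU	Europe
TR	Europe
JP	Asia
CN	Asia
KR	Asia
IN	Asia
TW	Asia
HK	Asia
SG	Asia
TH	Asia
MY	Asia
PH	Asia
ID	Asia
VN	Asia
IL	Asia
SA	Asia
AE	Asia
AU	Oceania
NZ	Oceania
ZA	Africa
EG	Africa
NG	Africa
KE	Africa
MA	Africa
TN	Africa
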