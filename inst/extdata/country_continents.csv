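code,continent
AD,Europe
AE,Asia
AF,Asia
AG,Americas
AL,Europe
AM,Asia
AO,Africa
AR,Americas
AT,Europe
AU,Oceania
AZ,Asia
BA,Europe
BB,Americas
BD,Asia
BE,Europe
BF,Africa
BG,Europe
BH,Asia
BI,Africa
BJ,Africa
BN,Asia
BO,Americas
BR,Americas
BS,Americas
BT,Asia
BW,Africa
BY,Europe
BZ,Americas
CA,Americas
CD,Africa
CF,Africa
CG,Africa
CH,Europe
CI,Africa
CL,Americas
CM,Africa
CN,Asia
CO,Americas
CR,Americas
CU,Americas
CV,Africa
CY,Europe
CZ,Europe
DE,Europe
DJ,Africa
DK,Europe
DM,Americas
DO,Americas
DZ,Africa
EC,Americas
EE,Europe
EG,Africa
ER,Africa
ES,Europe
ET,Africa
FI,Europe
FJ,Oceania
FM,Oceania
FR,Europe
GA,Africa
GB,Europe
GD,Americas
GE,Asia
GH,Africa
GM,Africa
GN,Africa
GQ,Africa
GR,Europe
GT,Americas
GW,Africa
GY,Americas
HK,Asia
HN,Americas
HR,Europe
HT,Americas
HU,Europe
ID,Asia
IE,Europe
IL,Asia
IN,Asia
IQ,Asia
IR,Asia
IS,Europe
IT,Europe
JM,Americas
JO,Asia
JP,Asia
KE,Africa
KG,Asia
KH,Asia
KI,Oceania
KM,Africa
KN,Americas
KP,Asia
KR,Asia
KW,Asia
KZ,Asia
LA,Asia
LB,Asia
LC,Americas
LI,Europe
LK,Asia
LR,Africa
LS,Africa
LT,Europe
LU,Europe
LV,Europe
LY,Africa
MA,Africa
MC,Europe
MD,Europe
ME,Europe
MG,Africa
MH,Oceania
MK,Europe
ML,Africa
MM,Asia
MN,Asia
MO,Asia
MR,Africa
MT,Europe
MU,Africa
MV,Asia
MW,Africa
MX,Americas
MY,Asia
MZ,Africa
NA,Africa
NE,Africa
NG,Africa
NI,Americas
NL,Europe
NO,Europe
NP,Asia
NR,Oceania
NZ,Oceania
OM,Asia
PA,Americas
PE,Americas
PG,Oceania
PH,Asia
PK,Asia
PL,Europe
PS,Asia
PT,Europe
PW,Oceania
PY,Americas
QA,Asia
RO,Europe
RS,Europe
RU,Europe
RW,Africa
SA,Asia
SB,Oceania
SC,Africa
SD,Africa
SE,Europe
SG,Asia
SI,Europe
SK,Europe
SL,Africa
SM,Europe
SN,Africa
SO,Africa
SR,Americas
SS,Africa
ST,Africa
SV,Americas
SY,Asia
SZ,Africa
TD,Africa
TG,Africa
TH,Asia
TJ,Asia
TL,Asia
TM,Asia
TN,Africa
TO,Oceania
TR,Asia
TT,Americas
TV,Oceania
TW,Asia
TZ,Africa
UA,Europe
UG,Africa
US,Americas
UY,Americas
UZ,Asia
VC,Americas
VE,Americas
VN,Asia
VU,Oceania
WS,Oceania
YE,Asia
ZA,Africa
ZM,Africa
ZW,Africa
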