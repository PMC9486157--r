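country,region
US,North America
USA,North America
UNITED STATES,North America
UNITED STATES OF AMERICA,North America
CA,North America
CANADA,North America
MX,North America
MEXICO,North America
CU,North America
GT,North America
PA,North America
CR,North America
DO,North America
JM,North America
PR,North America
GB,Europe
UNITED KINGDOM,Europe
FR,Europe
FRANCE,Europe
DE,Europe
GERMANY,Europe
IT,Europe
ITALY,Europe
ES,Europe
SPAIN,Europe
PT,Europe
NL,Europe
NETHERLANDS,Europe
BE,Europe
CH,Europe
AT,Europe
SE,Europe
NO,Europe
DK,Europe
FI,Europe
IE,Europe
PL,Europe
CZ,Europe
SK,Europe
HU,Europe
RO,Europe
BG,Europe
GR,Europe
HR,Europe
SI,Europe
RS,Europe
UA,Europe
RU,Europe
RUSSIAN FEDERATION,Europe
TR,Europe
IS,Europe
LU,Europe
MT,Europe
CY,Europe
EE,Europe
LV,Europe
LT,Europe
CN,Asia
CHINA,Asia
JP,Asia
JAPAN,Asia
KR,Asia
KOREA,Asia
REPUBLIC OF KOREA,Asia
IN,Asia
INDIA,Asia
ID,Asia
TH,Asia
VN,Asia
PH,Asia
MY,Asia
SG,Asia
TW,Asia
HK,Asia
PK,Asia
BD,Asia
LK,Asia
NP,Asia
IR,Asia
IQ,Asia
IL,Asia
SA,Asia
AE,Asia
JO,Asia
LB,Asia
KW,Asia
QA,Asia
KZ,Asia
UZ,Asia
EG,Africa
EGYPT,Africa
ZA,Africa
SOUTH AFRICA,Africa
NG,Africa
NIGERIA,Africa
KE,Africa
ET,Africa
GH,Africa
TZ,Africa
UG,Africa
DZ,Africa
MA,Africa
TN,Africa
LY,Africa
SD,Africa
CM,Africa
CI,Africa
SN,Africa
ZW,Africa
ZM,Africa
AO,Africa
MZ,Africa
AU,Oceania
AUSTRALIA,Oceania
NZ,Oceania
NEW ZEALAND,Oceania
FJ,Oceania
PG,Oceania
BR,South America
BRAZIL,South America
AR,South America
ARGENTINA,South America
CL,South America
CHILE,South America
CO,South America
COLOMBIA,South America
PE,South America
VE,South America
EC,South America
BO,South America
PY,South America
UY,South America
GY,South America
SR,South America
COUNTRY NOT SPECIFIED,Unknown
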