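state,climate_region
CT,Northeast
DE,Northeast
DC,Northeast
ME,Northeast
MD,Northeast
MA,Northeast
NH,Northeast
NJ,Northeast
NY,Northeast
PA,Northeast
RI,Northeast
VT,Northeast
IA,Upper Midwest
MI,Upper Midwest
MN,Upper Midwest
WI,Upper Midwest
IL,Ohio Valley
IN,Ohio Valley
KY,Ohio Valley
MO,Ohio Valley
OH,Ohio Valley
TN,Ohio Valley
WV,Ohio Valley
AL,Southeast
FL,Southeast
GA,Southeast
NC,Southeast
SC,Southeast
VA,Southeast
AR,South
KS,South
LA,South
MS,South
OK,South
TX,South
AZ,Southwest
CO,Southwest
NM,Southwest
UT,Southwest
MT,Northern Rockies and Plains
NE,Northern Rockies and Plains
ND,Northern Rockies and Plains
SD,Northern Rockies and Plains
WY,Northern Rockies and Plains
ID,Northwest
OR,Northwest
WA,Northwest
CA,West
NV,West
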