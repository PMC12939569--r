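sequence	activity	ic50_um	source
PR	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AY	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AF	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AP	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
VG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
MG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
WG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
QG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AI	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
EG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
NG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
PG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AR	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
PT	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AH	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
EK	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
DF	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
WL	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
PPL	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
ER	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
DR	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
AK	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
WY	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-1 hydrolysate
IR	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
MF	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
VY	ACE inhibitor	5.2	database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
PL	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
VK	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
IG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
VR	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
QK	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
DG	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
NF	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
NK	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
EY	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
PH	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
DY	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
DM	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
IL	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
EF	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
DL	ACE inhibitor		database-verified dipeptide/tripeptide released from collagen alpha-2 hydrolysate
PPG	ACE inhibitor		literature: 23.14% inhibition at 1000 uL/mL
APG	ACE inhibitor		literature: activity confirmed, no parameters
PK	ACE inhibitor	4092	literature
CDF	ACE inhibitor	192.17	literature
IPI	DPP-IV inhibitor		literature: diprotin A
GP	DPP-IV inhibitor		database-verified dipeptide
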