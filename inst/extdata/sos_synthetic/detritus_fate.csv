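group,DC,SPOM,BD
SB,0,1,0
MM,0,1,0
TUR,0,1,0
XIP,0,1,0
THU,0,1,0
LPL,0,1,0
MPL,0,1,0
SPL,0,1,0
HAK0,0,0,1
HAK1,0,0,1
HAK2,0,0,1
HAK3,0,0,1
HAK4,0,0,1
MUL0,0,0,1
MUL1,0,0,1
MUL2,0,0,1
MUL3,0,0,1
TRA,0,0,1
PAG,0,0,1
DFS,0,0,1
DFH,0,0,1
DSM,0,0,1
DSP,0,0,1
DSR,0,0,1
MSC,0,0,1
MSG,0,0,1
MSP,0,0,1
RSH,0,0,1
RSS,0,0,1
SSH,0,0,1
SSS,0,0,1
ENG,0,1,0
SAR,0,1,0
EPI,0,1,0
CEBH,0,0,1
CEBS,0,0,1
CEPH,0,0,1
CEPS,0,0,1
DNS,0,0,1
DNH,0,0,1
DRS,0,0,1
DRH,0,0,1
ARF,0,0,1
PWL,0,0,1
SUP,0,0,1
O,0,0,1
FF,0,0,1
DF,0,0,1
C,0,0,1
PAR,0,0,1
SCA,0,0,1
H,0,0,1
GRA,0,0,1
SF,0,0,1
PF,0,0,1
BO,0,0,1
EUP,0,1,0
ZG,0,1,0
ZL,0,1,0
ZM,0,1,0
ZS,0,1,0
PB,0,1,0
BB,0,0,1
PS,0,1,0
DFL,0,1,0
PL,0,1,0
MB,0,0,1
SG,0,0,1
MA,0,0,1
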