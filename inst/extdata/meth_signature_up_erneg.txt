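ACN9
ADORA2B
AKR1B1
ALDH1A3
ANKH
CAV2
CHST11
CPNE8
EGFR
EPHB2
FMNL2
FOSL1
GPX1
HS3ST1
IGF2BP2
IGF2BP3
KIFC3
LYN
MALL
MSN
NEXN
NPAS2
PLAC8
PPARG
RIN3
SEMA7A
SLC19A3
TEC
TXNRD1
UPP1
VLDLR
ZNF502
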