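ACOT4
CUX2
MPPED2
SEPT5
ADAMTS13
CXCL12
MPV17L
SIDT2
ADAMTS19
CXXC5
MSI1
SLC16A6
ADCY1
DNAJA4
MYRIP
SLC16A9
AMPH
DSCAML1
NAAA
SLC1A2
AMZ2
ENTPD2
NKD2
SLC29A4
AR
FGFR4
NOVA1
SLITRK4
ASCL2
FKBP4
NPEPL1
SPATA2L
ASTN2
FSCN2
NPNT
SPATA7
ATP2A3
GATA3
NPTXR
SPNS1
ATP8B2
GFRA1
P2RX2
SRMS
BTG2
GHR
PALM
ST6GALNAC2
C16orf14
GJD3
PATZ1
STK32B
C17orf28
GPR160
PAX9
STOM
C20orf134
GRIK3
PCP4L1
SYCP2
C3orf57
HS6ST3
PDZRN3
TMEM47
C6orf154
ID2
PGR
TRPV4
C6orf97
IFT140
PLCB1
VPS37D
CA8
IGFBP2
PRKCZ
ZNF396
CACNA1H
IGSF9B
PRKG1
ZNF512B
CACNA2D2
IL17RB
PRUNE2
ZNF703
CADM1
JAM2
PSTPIP2
CAMK2B
KCNH1
PTGER3
CASKIN1
KCNK6
RAPGEFL1
CELSR1
KCNMA1
RHBG
CGREF1
KIF12
RHOT2
CHDH
KIFC2
RICH2
CHST1
KLHDC9
RND2
CLUAP1
LMX1B
RNF40
CNTNAP2
LRRC26
SAMD11
CPLX1
MAPK8IP2
SDC2
CRIP2
MMP17
SEMA6A
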