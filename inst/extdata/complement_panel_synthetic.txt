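C1QA
C1R
C1RL
C1S
C2
C3
C4BPB
C5
C7
CD46
CD55
CFB
CFD
CFH
CFHR2
CFHR4
CFHR5
CFI
CFP
CLU
CR1
CR2
FCN1
FCN2
MASP1
MASP2
MBL2
SERPING1
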