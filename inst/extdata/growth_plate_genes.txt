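Gli2
Tcf7
Runx2
Sox9
MEF2C
STAT1
ATF2
NFkB
CCND1
Dlx5
Ets1
dEF1
HIF2a
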