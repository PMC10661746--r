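drug,ed50,sem,n,source
CBZ,9.52,NA,16,printed
PHT,8.71,NA,16,printed
PB,28.85,NA,16,printed
VPA,292,NA,24,printed
ISOP,235.7,23.5,28,printed
BOR,250,NA,28,inferred
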