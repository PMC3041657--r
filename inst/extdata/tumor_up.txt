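ITGA3
ITGB1
CDH1
EPCAM
KRT18
KRT8
VIM
FN1
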