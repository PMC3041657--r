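VIM
FN1
SNAI2
ZEB1
TWIST1
CDH2
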