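Source Target Type
miR200 ZEB 2
ZEB miR200 2
ZEB GRHL2 2
GRHL2 ZEB 2
SNAIL miR200 2
SNAIL ZEB 1
ZEB ZEB 1
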