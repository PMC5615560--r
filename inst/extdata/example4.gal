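4
a 2
b c
b 2
a d
c 2
a d
d 2
b c
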