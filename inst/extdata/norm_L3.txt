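# norm: L3
a_1C1 = 1
a_1D1 = 0
a_1C0 = 1
a_1D0 = 1
a_0C1 = 1
a_0D1 = 0
a_0C0 = 1
a_0D0 = 1
b_11 = 1
b_10 = 0
b_01 = 1
b_00 = 0
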