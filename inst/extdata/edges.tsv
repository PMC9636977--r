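source	target	gamma
u1	u2	0.29999999999999999
u1	u4	-0.14999999999999999
u3	u2	0.20000000000000001
u4	u5	0.25
u6	u5	-0.10000000000000001
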