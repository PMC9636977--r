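id,z,Y
u1,1,2.6000000000000001
u2,0,1.7
u3,0,3.2000000000000002
u4,0,0.65000000000000002
u5,1,2.1999999999999997
u6,1,3.2000000000000002
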