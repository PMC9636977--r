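id,alpha,beta
u1,2.1000000000000001,0.5
u2,1.3999999999999999,0.80000000000000004
u3,3.2000000000000002,0.29999999999999999
u4,0.80000000000000004,0.90000000000000002
u5,1.8999999999999999,0.40000000000000002
u6,2.6000000000000001,0.59999999999999998
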