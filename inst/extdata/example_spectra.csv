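sample_id,replicate_id,label,1000,1002,1004,1006,1008,1010
s01,1,1,0.112,0.135,0.171,0.198,0.176,0.141
s01,2,1,0.109,0.133,0.168,0.195,0.174,0.139
s01,3,1,0.114,0.137,0.173,0.200,0.178,0.143
s02,1,0,0.098,0.118,0.149,0.171,0.152,0.122
s02,2,0,0.101,0.121,0.152,0.174,0.155,0.125
s02,3,0,0.097,0.117,0.148,0.170,0.151,0.121
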