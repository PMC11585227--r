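subject,group,time,value
G1.1,G1,T1,1
G1.2,G1,T1,2
G1.3,G1,T1,4
G1.4,G1,T1,3
G1.1,G1,T2,3
G1.2,G1,T2,
G1.3,G1,T2,2
G1.4,G1,T2,5
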