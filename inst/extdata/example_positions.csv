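time_s,subject,x,y
0,f1,10,10
0.2,f1,12,10
0.4,f1,12,13
0.6,f1,15,13
0.8,f1,15,17
1,f1,18,17
0,f2,5,5
0.2,f2,5,5
0.4,f2,5,5
0.8,f2,5,5
1,f2,5,5
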