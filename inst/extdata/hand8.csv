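id,start,stop,event,x,z
1,0,1,0,1,0.5
1,1,2,1,1,0.8
2,0,2,0,0,1.2
2,2,3,1,0,1.0
3,0,1.5,1,1,0.2
4,0,2,0,0,0.7
4,2,4,0,0,0.9
5,0,1.5,1,0,1.1
6,0,3,1,1,0.4
7,0,1,0,1,1.5
7,1,4,0,1,1.3
8,0,2.5,1,0,0.6
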