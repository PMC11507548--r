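study,spre,model,spost,dstruct,phi,valid
1,1,1,1,1,0.637,TRUE
2,1,1,1,2,0.994,TRUE
3,1,1,2,1,0.637,TRUE
4,1,1,2,2,0.994,TRUE
5,1,2,1,1,0.873,TRUE
6,1,2,1,2,0.944,TRUE
7,1,2,2,1,0.976,TRUE
8,1,2,2,2,0.990,TRUE
9,2,1,1,1,0,FALSE
10,2,1,1,2,0,FALSE
11,2,1,2,1,0,FALSE
12,2,1,2,2,0,FALSE
13,2,2,1,1,0.878,TRUE
14,2,2,1,2,0.950,TRUE
15,2,2,2,1,0.976,TRUE
16,2,2,2,2,0.990,TRUE
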