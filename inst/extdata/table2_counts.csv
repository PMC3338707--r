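unit,control,treatment,irr
1,14,10,0.71
2,17,7,0.41
3,8,3,0.38
4,6,4,0.67
5,11,5,0.45
6,20,7,0.35
7,12,15,1.25
8,5,5,1.00
9,4,4,1.00
10,9,8,0.89
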