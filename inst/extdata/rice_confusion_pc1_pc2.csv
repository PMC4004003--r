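true,P36,WT025,XW13,YPX,YY122,ZX1
P36,5,0,0,0,0,0
WT025,0,4,0,0,1,0
XW13,0,0,5,0,0,0
YPX,0,0,0,5,0,0
YY122,0,0,2,0,3,0
ZX1,0,0,0,0,0,5
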