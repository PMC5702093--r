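code,recode,label
0,0,independent
1,0,setup help only
2,1,supervision
3,2,limited assistance
4,3,extensive assistance
5,3,maximal assistance
6,4,total dependence
8,4,activity did not occur
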