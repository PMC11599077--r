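dose,label,count
0,0,447
1,1,80
2,2,248
3,3,123
4,4,65
5,5 or more,57
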