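threshold,dataset,stage,n,INA,ACT
6,TS,start,6371,5388,983
6,VS,start,1592,1346,246
6,ES,start,792,676,116
6,VS,in_ad,1583,1338,245
6,ES,in_ad,754,642,112
5,TS,start,6371,3295,3076
5,VS,start,1592,821,771
5,ES,start,792,365,427
5,VS,in_ad,1579,810,769
5,ES,in_ad,754,350,404
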