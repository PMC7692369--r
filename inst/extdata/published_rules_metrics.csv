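class,rule,support,strength,confirmation
1,1,32,0.1777,0.75
1,2,46,0.2555,0.75
1,3,43,0.2388,0.73
1,4,47,0.2611,0.73
1,5,48,0.2666,0.73
1,6,33,0.1833,0.72
1,7,36,0.2000,0.72
1,8,36,0.2000,0.72
1,9,39,0.2166,0.72
1,10,41,0.2277,0.72
1,11,50,0.2777,0.72
1,12,34,0.1888,0.70
1,13,37,0.2055,0.70
1,14,41,0.2277,0.70
1,15,53,0.2944,0.70
1,16,21,0.1166,0.69
1,17,32,0.1777,0.69
1,18,43,0.2388,0.69
1,19,43,0.2388,0.69
1,20,47,0.2611,0.69
2,1,30,0.1666,0.70
2,2,48,0.2666,0.70
2,3,42,0.2333,0.70
2,4,43,0.2388,0.70
2,5,31,0.1722,0.70
2,6,37,0.2055,0.69
2,7,42,0.2333,0.67
2,8,31,0.1722,0.67
2,9,23,0.1277,0.67
2,10,23,0.1277,0.67
2,11,31,0.1722,0.67
2,12,41,0.2277,0.66
2,13,30,0.1666,0.66
2,14,37,0.2055,0.66
2,15,35,0.1944,0.66
2,16,42,0.2333,0.65
2,17,36,0.2000,0.65
2,18,33,0.1833,0.65
2,19,36,0.2000,0.65
2,20,34,0.1888,0.65
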