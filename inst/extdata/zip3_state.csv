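zip3,state
010,MA
021,MA
022,MA
024,MA
100,NY
104,NY
112,NY
146,NY
191,PA
152,PA
303,GA
306,GA
331,FL
327,FL
336,FL
441,OH
432,OH
553,MN
554,MN
606,IL
604,IL
631,MO
641,MO
750,TX
770,TX
782,TX
802,CO
803,CO
850,AZ
852,AZ
890,NV
891,NV
900,CA
941,CA
921,CA
972,OR
973,OR
980,WA
981,WA
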