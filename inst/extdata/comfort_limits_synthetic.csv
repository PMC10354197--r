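frequency_hz,limit_ms2,duration_h
0.5,1.4990663761154808,4
0.63,1.3354744712992697,4
0.8,1.1851160280748887,4
1,1.06,4
1.25,0.9480928224599109,4
1.6,0.8380035799446205,4
2,0.7495331880577404,4
2.5,0.6704028639556965,4
3.15,0.5972423400081517,4
4,0.53,4
5,0.53,4
6.3,0.53,4
8,0.53,4
10,0.6625000000000001,4
12.5,0.828125,4
16,1.06,4
20,1.3250000000000002,4
0.5,0.8909545442950498,8
0.63,0.7937253933193772,8
0.8,0.7043614129124338,8
1,0.63,8
1.25,0.563489130329947,8
1.6,0.4980587314765197,8
2,0.4454772721475249,8
2.5,0.3984469851812158,8
3.15,0.35496478698597694,8
4,0.315,8
5,0.315,8
6.3,0.315,8
8,0.315,8
10,0.39375,8
12.5,0.4921875,8
16,0.63,8
20,0.7875,8
0.5,0.565685424949238,16
0.63,0.5039526306789697,16
0.8,0.447213595499958,16
1,0.4,16
1.25,0.35777087639996635,16
1.6,0.31622776601683794,16
2,0.282842712474619,16
2.5,0.2529822128134704,16
3.15,0.2253744679276044,16
4,0.2,16
5,0.2,16
6.3,0.2,16
8,0.2,16
10,0.25,16
12.5,0.3125,16
16,0.4,16
20,0.5,16
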