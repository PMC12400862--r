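section,distance_m,elevation_gain_m
1,2231,0.0
2,8369,470.7
3,884,-7.5
4,1180,52.7
5,2494,-158.2
6,1476,139.3
7,2657,-11.3
8,8893,-482.0
9,5579,0.0
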