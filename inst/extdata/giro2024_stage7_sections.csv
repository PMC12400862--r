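section,distance_m,elevation_gain_m
1,5343,-19.8
2,1835,14.8
3,5182,-28.7
4,5440,23.7
5,4957,-23.7
6,5601,4.0
7,1416,24.7
8,676,-34.6
9,3412,10.9
10,1545,145.3
11,5472,117.6
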