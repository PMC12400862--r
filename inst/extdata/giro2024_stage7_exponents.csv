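section,x_opt,mean_duration_s
1,0.3818,409.58
2,0.4904,156.51
3,0.3798,390.71
4,0.4449,448.27
5,0.3807,376.54
6,0.3957,446.27
7,0.5920,132.60
8,0.3498,37.03
9,0.4288,278.00
10,0.8781,314.53
11,0.6287,533.86
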