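section,x_opt,mean_duration_s
1,0.3854,176.52
2,0.8168,1182.92
3,0.3764,64.95
4,0.7748,147.43
5,0.3453,127.90
6,0.8779,300.83
7,0.3814,202.61
8,0.3483,479.01
9,0.3854,441.43
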