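"ach","numerical_open","numerical_closed","analytical","difference_pct_open","difference_pct_closed"
0.3,195.65,213.7,221.6,11.71,3.56
0.5,124.07,130.37,138.22,10.23,5.68
1,66.25,70.21,74.59,11.17,5.87
1.5,47.07,50.33,53.17,11.46,5.34
2,37.76,40.1,42.42,10.97,5.47
4.3,20.17,23.32,25.11,19.67,7.11
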