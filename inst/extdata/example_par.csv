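time_h,par
0,0
1.5,0
3,0
4.5,0
6,133.513
7.5,319.219
9,469.099
10.5,566.33
12,600
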