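number,act,pls_pred,enpls_pred
1,108.33,100.04,95.66
2,105.95,109.26,101.16
3,107.54,121.08,150.84
4,100.00,95.54,110.57
5,100.79,94.68,97.03
6,89.68,103.86,101.68
7,91.27,105.41,87.64
8,85.32,121.30,103.43
9,101.87,85.91,104.86
10,102.25,111.26,104.34
11,108.61,96.89,112.05
12,116.10,102.6,107.22
13,91.76,96.31,90.37
14,92.13,99.56,100.61
15,82.83,82.06,86.56
16,82.53,85.69,82.04
17,115.58,120.84,122.50
18,120.29,115.73,125.46
19,135.14,126.63,136.89
20,126.45,110.55,121.62
21,122.46,104.37,116.80
22,121.38,129.29,113.11
23,119.20,122.39,133.17
24,102.41,120.91,99.67
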