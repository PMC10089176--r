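dataset,logml_default,sd_default,logml_alternative,sd_alternative,two_ln_bf
1,-187.65,0.12,-147.32,0.11,80.67
2,-142.52,0.04,-128.76,0.04,27.53
3,-214.89,0.12,-174.02,0.07,81.76
4,-106.20,0.03,-91.47,0.12,29.46
5,-1176.37,0.24,-1037.50,0.04,277.75
6,-1309.05,0.12,-1164.72,0.04,288.65
7,-835.94,0.30,-726.80,0.15,218.29
8,-2873.90,0.42,-2275.48,0.04,1196.85
9,-2333.80,0.69,-1872.88,0.02,921.84
10,-305.88,0.12,-258.13,0.15,95.79
11,-2519.33,0.12,-2159.85,0.31,718.97
12,-1983.57,0.35,-1721.13,0.12,524.88
13,-1754.35,0.04,-1536.92,0.04,434.88
14,-1372.08,0.09,-1225.46,0.24,293.24
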