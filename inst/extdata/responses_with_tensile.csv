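run,experimental,predicted_rsm,predicted_bo
1,47.54,50.43,40.51
2,73.10,65.45,48.14
3,12.86,13.48,11.62
4,24.37,28.51,21.38
5,23.85,23.33,26.62
6,39.69,38.36,37.40
7,21.89,18.89,24.44
8,29.07,33.91,30.98
9,47.43,49.42,45.17
10,12.61,12.47,16.71
11,42.21,44.98,40.57
12,12.65,8.03,12.64
13,31.90,27.44,29.40
14,29.61,27.44,29.40
15,20.80,27.44,29.40
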