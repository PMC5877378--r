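subject,scheme,movie,self,cross
1,binary,93.33,87.48,82.99
2,binary,99.84,98.91,87.21
3,binary,97.01,99.73,95.51
4,binary,90.20,88.71,86.94
5,binary,94.01,82.59,93.61
6,binary,97.41,85.17,86.12
7,binary,93.47,76.46,78.91
8,binary,99.86,99.32,93.06
9,binary,86.94,82.04,73.33
10,binary,74.69,96.05,80.14
11,binary,89.93,87.62,80.95
12,binary,87.48,92.65,81.63
13,binary,89.52,77.14,48.84
14,binary,67.89,68.16,69.93
15,binary,92.65,90.20,88.98
16,binary,82.04,65.58,50.07
17,binary,77.69,94.69,56.05
18,binary,86.26,79.05,88.44
19,binary,71.70,82.72,96.46
20,binary,87.07,90.07,79.32
21,binary,69.52,85.17,81.90
22,binary,79.18,85.71,31.02
23,binary,93.20,87.35,48.57
24,binary,87.21,90.88,82.85
25,binary,86.80,87.35,60.14
26,binary,97.96,97.82,99.32
27,binary,88.98,86.12,80.82
28,binary,89.93,92.80,89.93
29,binary,86.53,91.43,98.78
30,binary,77.69,91.84,84.08
1,six_class,65.65,63.04,65.65
2,six_class,65.87,56.24,47.28
3,six_class,56.01,63.72,50.00
4,six_class,39.68,57.71,66.55
5,six_class,51.93,50.45,69.05
6,six_class,55.10,53.74,42.06
7,six_class,57.03,40.82,33.79
8,six_class,72.45,71.77,47.51
9,six_class,41.27,64.29,40.93
10,six_class,52.39,39.57,54.20
11,six_class,56.92,52.95,39.68
12,six_class,60.32,54.20,46.94
13,six_class,39.46,46.15,40.36
14,six_class,41.38,58.05,64.51
15,six_class,54.42,56.69,41.27
16,six_class,43.65,40.82,41.95
17,six_class,42.52,60.66,46.71
18,six_class,65.99,44.67,51.25
19,six_class,49.89,64.29,56.92
20,six_class,60.20,55.33,31.07
21,six_class,73.24,70.52,29.48
22,six_class,41.27,41.16,42.74
23,six_class,60.54,29.59,48.64
24,six_class,58.50,58.50,60.54
25,six_class,51.70,47.05,26.76
26,six_class,81.52,82.54,85.94
27,six_class,62.13,64.63,51.47
28,six_class,55.22,49.43,48.30
29,six_class,59.52,44.78,69.16
30,six_class,53.63,52.38,56.92
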