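# synthetic astrocyte arbor (generated fixture, not a real reconstruction)
# id type x y z radius parent
1 1 0 0 0 4 -1
2.00 3.00 10.68 -4.40 2.83 2.50 1.00
3.00 3.00 -6.54 3.19 3.43 2.50 1.00
4.00 3.00 -0.62 13.21 -0.41 2.50 1.00
5.00 3.00 -7.40 10.99 0.24 2.50 1.00
6.00 3.00 -1.13 5.41 -2.42 2.50 1.00
7.00 3.00 -17.86 7.92 5.27 1.75 3.00
8.00 3.00 5.47 18.14 0.58 1.75 4.00
9.00 3.00 -3.01 7.21 2.96 1.75 4.00
10.00 3.00 -7.81 17.04 4.40 1.75 5.00
11.00 3.00 -4.37 11.96 -8.02 1.75 5.00
12.00 3.00 -0.38 6.52 -8.82 1.75 6.00
13.00 3.00 -20.43 10.50 -0.42 1.22 7.00
14.00 3.00 -0.77 23.01 2.30 1.22 8.00
15.00 3.00 13.89 23.73 -3.31 1.22 8.00
16.00 3.00 -6.13 11.08 8.97 1.22 10.00
17.00 3.00 -7.70 10.45 6.98 1.22 10.00
18.00 3.00 -1.01 16.37 -5.04 1.22 11.00
19.00 3.00 2.43 14.66 -3.67 1.22 11.00
20.00 3.00 -18.06 5.90 -6.92 0.86 13.00
21.00 3.00 19.82 22.42 -5.35 0.86 15.00
22.00 3.00 -3.79 4.67 11.52 0.86 16.00
23.00 3.00 -3.72 7.61 11.36 0.86 16.00
24.00 3.00 -3.51 2.78 8.19 0.86 17.00
25.00 3.00 3.53 23.38 -5.05 0.86 18.00
26.00 3.00 4.31 23.10 -5.43 0.86 18.00
27.00 3.00 0.61 7.54 -7.53 0.86 19.00
28.00 3.00 23.24 20.32 -2.69 0.60 21.00
29.00 3.00 20.95 23.15 -12.86 0.60 21.00
30.00 3.00 -4.43 8.91 4.51 0.60 22.00
31.00 3.00 -4.24 0.85 7.90 0.60 22.00
32.00 3.00 -3.77 13.35 8.85 0.60 23.00
33.00 3.00 -5.24 -1.20 8.64 0.60 24.00
34.00 3.00 -6.49 6.43 4.24 0.60 24.00
35.00 3.00 6.94 25.70 -4.31 0.60 25.00
36.00 3.00 11.56 22.06 -8.26 0.60 26.00
37.00 3.00 2.03 2.66 -9.74 0.60 27.00
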