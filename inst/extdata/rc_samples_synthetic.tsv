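# Synthetic analyzer rocking-curve samples (NOT measured data).
# Unit-peak Gaussian, sigma = 8.6 urad, peak 12000 counts, 0.5% noise, fixed seed.
# columns: angle_urad  intensity_counts
-30 27
-29 41
-28 60
-27 87
-26 124
-25 175
-24 244
-23 334
-22 455
-21 614
-20 801
-19 1042
-18 1344
-17 1700
-16 2120
-15 2593
-14 3186
-13 3858
-12 4558
-11 5318
-10 6055
-9 6923
-8 7808
-7 8601
-6 9470
-5 10159
-4 10768
-3 11263
-2 11653
-1 11926
0 12056
1 11815
2 11617
3 11300
4 10832
5 10089
6 9408
7 8505
8 7732
9 6964
10 6105
11 5326
12 4536
13 3819
14 3195
15 2614
16 2133
17 1698
18 1348
19 1045
20 806
21 608
22 454
23 337
24 244
25 176
26 124
27 87
28 60
29 41
30 28
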