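# x U_kJmol
0.455 121.7217
0.46 104.3655
0.465 89.37975
0.47 76.64458
0.475 65.74771
0.48 56.27894
0.485 48.11825
0.49 41.10881
0.495 34.98397
0.5 29.75366
0.505 25.20752
0.51 21.31638
0.515 17.94616
0.52 14.9678
0.525 12.46373
0.53 10.27009
0.535 8.450939
0.54 6.884334
0.545 5.644916
0.55 4.546577
0.555 3.581421
0.56 2.848629
0.565 2.269564
0.57 1.768024
0.575 1.331917
0.58 0.9727028
0.585 0.6831181
0.59 0.4464112
0.595 0.2948355
0.6 0.1757855
0.605 0.09429493
0.61 0.1283311
0.615 0.06342178
0.62 0
0.625 0.0691306
0.63 0.1736717
0.635 0.1891582
0.64 0.1511054
0.645 0.2963231
0.65 0.366317
0.655 0.4511968
0.66 0.5130197
0.665 0.5916141
0.67 0.7014926
0.675 0.7838171
0.68 0.9027152
0.685 0.9974639
0.69 1.128102
0.695 1.237644
0.7 1.235835
0.705 1.367203
0.71 1.485287
0.715 1.522867
0.72 1.661555
0.725 1.735524
0.73 1.83277
0.735 1.95902
0.74 1.997414
0.745 2.095058
0.75 2.14053
0.755 2.2148
0.76 2.269043
0.765 2.353619
0.77 2.419333
0.775 2.50041
0.78 2.53732
0.785 2.596763
0.79 2.666027
0.795 2.725864
0.8 2.798762
0.805 2.812623
0.81 2.906925
0.815 2.915826
0.82 2.962551
0.825 2.99843
0.83 3.059235
0.835 3.132126
0.84 3.16173
0.845 3.190197
0.85 3.271358
0.855 3.283491
0.86 3.347621
0.865 3.349462
0.87 3.357085
0.875 3.44966
0.88 3.440285
0.885 3.451393
0.89 3.478713
0.895 3.604877
0.9 3.586326
0.905 3.614843
0.91 3.622741
0.915 3.700281
0.92 3.671026
0.925 3.73916
0.93 3.716274
0.935 3.65714
0.94 3.782858
0.945 3.799903
0.95 3.795006
0.955 3.835635
0.96 3.845751
0.965 3.868736
0.97 3.85608
0.975 3.888381
0.98 3.892276
0.985 3.927299
0.99 3.995871
0.995 3.922552
1 3.931037
1.005 3.972874
1.01 4.032898
1.015 4.032337
1.02 4.025339
1.025 4.05986
1.03 4.06012
1.035 4.110109
1.04 4.07944
1.045 4.08291
1.05 4.112195
1.055 4.058631
1.06 4.163211
1.065 4.103577
1.07 4.111082
1.075 4.15394
1.08 4.131118
1.085 4.19011
1.09 4.174034
1.095 4.234552
1.1 4.17334
1.105 4.155453
1.11 4.195257
1.115 4.200585
1.12 4.187714
1.125 4.196897
1.13 4.226356
1.135 4.191222
1.14 4.197422
1.145 4.234025
1.15 4.222842
1.155 4.244636
1.16 4.27609
1.165 4.227778
1.17 4.236065
1.175 4.284369
1.18 4.247745
1.185 4.303364
1.19 4.28079
1.195 4.261649
1.2 4.301165
1.205 4.252352
1.21 4.286641
1.215 4.23657
1.22 4.285602
1.225 4.367695
1.23 4.36158
1.235 4.315897
1.24 4.313117
1.245 4.310796
1.25 4.343408
1.255 4.270981
1.26 4.302716
1.265 4.320515
1.27 4.372977
1.275 4.312515
1.28 4.359745
1.285 4.334854
1.29 4.26472
1.295 4.389853
1.3 4.297321
1.305 4.320709
1.31 4.321945
1.315 4.312798
1.32 4.315331
1.325 4.332353
1.33 4.281864
1.335 4.388869
1.34 4.318996
1.345 4.388222
1.35 4.369679
1.355 4.3982
1.36 4.395537
1.365 4.356787
1.37 4.348101
1.375 4.38667
1.38 4.427232
1.385 4.403205
1.39 4.378376
1.395 4.349709
1.4 4.381348
1.405 4.328979
1.41 4.341021
1.415 4.466411
1.42 4.425769
1.425 4.387239
1.43 4.347493
1.435 4.407357
1.44 4.426469
1.445 4.37569
1.45 4.394857
1.455 4.360534
1.46 4.370593
1.465 4.376205
1.47 4.352649
1.475 4.424781
1.48 4.42917
1.485 4.36868
1.49 4.38212
1.495 4.442053
1.5 4.481161
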